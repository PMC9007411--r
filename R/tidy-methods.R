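#' Tidy an EoS fit
#'
#' @param x An `eos_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `fixed`.
#' @method tidy eos_fit
#' @export
tidy.eos_fit <- function(x, ...) {
  x$params
}

#' One-row summary of an EoS fit
#'
#' @param x An `eos_fit`.
#' @param ... Unused.
#' @return A tibble: `family`, `v0`, `k0`, `kprime`, `n_points`, `rss`
#'   (weighted), `rms_p` (GPa).
#' @method glance eos_fit
#' @export
glance.eos_fit <- function(x, ...) {
  p <- setNames(x$params$estimate, x$params$term)
  tibble(
    family = x$family,
    v0 = p[["v0"]], k0 = p[["k0"]], kprime = p[["kprime"]],
    n_points = x$n_points,
    rss = sum(x$weights * x$residuals^2),
    rms_p = sqrt(mean(x$residuals^2))
  )
}

#' Observation-level results of an EoS fit
#'
#' @param x An `eos_fit`.
#' @param ... Unused.
#' @return The fitted data with `.fitted` (model pressure) and `.resid`.
#' @method augment eos_fit
#' @export
augment.eos_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- out$pressure - x$residuals
  out$.resid <- x$residuals
  out
}

#' Tidy a Monte Carlo volume result
#'
#' @param x A `volume_result`.
#' @param ... Unused.
#' @return One row per run: `run`, `v_net`.
#' @method tidy volume_result
#' @export
tidy.volume_result <- function(x, ...) {
  tibble(run = seq_along(x$per_run_v_net), v_net = x$per_run_v_net)
}

#' One-row summary of a Monte Carlo volume result
#'
#' @param x A `volume_result`.
#' @param ... Unused.
#' @return A tibble: `v_cell`, `v_net`, `v_void`, `sigma_net`, `x` (packing
#'   coefficient), `n_points`, `n_runs`, `converged`.
#' @method glance volume_result
#' @export
glance.volume_result <- function(x, ...) {
  res <- x
  tibble(
    v_cell = res$v_cell, v_net = res$v_net, v_void = res$v_void,
    sigma_net = res$sigma_net, x = res$v_net / res$v_cell,
    n_points = res$n_points, n_runs = res$n_runs, converged = res$converged
  )
}

#' Plot a pressure series with its volume components
#'
#' @param object A [pressure_series()].
#' @param components Which volume columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pressure_series
#' @export
autoplot.pressure_series <- function(object, components = c("net", "void", "cell"), ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(
    df[, c("pressure", paste0("v_", components))],
    -"pressure", names_to = "component", values_to = "volume",
    names_prefix = "v_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pressure, y = .data$volume, colour = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(
      x = "Pressure (GPa)", y = expression(Volume ~ (ring(A)^3)),
      title = attr(object, "id")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an EoS fit over its data
#'
#' @param object An `eos_fit`.
#' @param n_curve Points on the fitted curve.
#' @param ... Unused.
#' @return A ggplot of volume against pressure with the fitted curve.
#' @method autoplot eos_fit
#' @export
autoplot.eos_fit <- function(object, n_curve = 200, ...) {
  df <- object$data
  pg <- seq(min(df$pressure), max(df$pressure), length.out = n_curve)
  curve <- predict_eos_volume(object, pg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pressure, y = .data$volume)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Pressure (GPa)", y = expression(Volume ~ (ring(A)^3)),
      title = sprintf("%s fit: K0 = %.2f GPa", toupper(object$family),
                      object$params$estimate[object$params$term == "k0"])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a piecewise-fit break report
#'
#' @param object A `break_report` from [piecewise_fit()].
#' @param n_curve Points per fitted curve.
#' @param ... Unused.
#' @return A ggplot with the segment fits and the break marked.
#' @method autoplot break_report
#' @export
autoplot.break_report <- function(object, n_curve = 100, ...) {
  df <- series_component(object$series, object$component)
  curves <- dplyr::bind_rows(lapply(seq_along(object$fits), function(i) {
    f <- object$fits[[i]]
    pg <- seq(min(f$data$pressure), max(f$data$pressure), length.out = n_curve)
    out <- predict_eos_volume(f, pg)
    out$segment <- factor(i)
    out
  }))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pressure, y = .data$volume)) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$segment), linewidth = 0.7
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Pressure (GPa)", y = expression(Volume ~ (ring(A)^3)),
      title = sprintf("%s volume, %s", object$component, toupper(object$family))
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$break_pressure)) {
    g <- g + ggplot2::geom_vline(xintercept = object$break_pressure, linetype = 2)
  }
  g
}

#' @importFrom rlang .data
NULL
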