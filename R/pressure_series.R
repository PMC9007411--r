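#' Assemble a pressure series
#'
#' An ordered table of per-pressure volume partitions for one compound or
#' phase family: columns `pressure` (GPa, strictly increasing), `v_cell`,
#' `v_net`, `v_void` (cubic angstroms), `sigma` (standard deviation of
#' `v_net`) and `Z` (formula units per cell).
#'
#' @param records A data frame with at least `pressure`, `v_net` and one of
#'   `v_void`/`v_cell` (the missing one is completed by conservation);
#'   optional `sigma` (default 0) and `Z` (default 1).
#' @param id Identifier string.
#' @param scaled Whether volumes are already per formula unit.
#' @return A tibble of class `pressure_series` (attributes `id`, `scaled`).
#' @export
pressure_series <- function(records, id = "", scaled = FALSE) {
  df <- as_tibble(records)
  if (!all(c("pressure", "v_net") %in% names(df))) {
    abort("records must have columns 'pressure' and 'v_net'")
  }
  if (!"v_cell" %in% names(df) && !"v_void" %in% names(df)) {
    abort("records must have 'v_cell' or 'v_void'")
  }
  if (!"v_void" %in% names(df)) df$v_void <- df$v_cell - df$v_net
  if (!"v_cell" %in% names(df)) df$v_cell <- df$v_net + df$v_void
  if (!"sigma" %in% names(df)) df$sigma <- 0
  if (!"Z" %in% names(df)) df$Z <- 1
  df <- df[order(df$pressure), c("pressure", "v_cell", "v_net", "v_void", "sigma", "Z")]
  if (any(duplicated(df$pressure))) abort("duplicate pressures in series")
  if (any(df$pressure < 0)) abort("pressures must be non-negative")
  if (any(df$v_cell <= 0 | df$v_net <= 0 | df$v_void <= 0)) {
    abort("all volumes must be positive")
  }
  if (any(df$Z < 1) || any(df$Z != round(df$Z))) abort("Z must be a positive integer")
  structure(df, class = c("pressure_series", class(df)), id = id, scaled = scaled)
}

#' Assemble a series from per-pressure volume results
#'
#' @param results A list of `volume_result` objects, one per pressure.
#' @param pressures Pressures in GPa, same length as `results`.
#' @param Z Formula units per cell (scalar or per-record).
#' @param id Series identifier.
#' @return A [pressure_series()].
#' @export
assemble_series <- function(results, pressures, Z = 1, id = "") {
  if (length(results) != length(pressures)) {
    abort("results and pressures must have the same length")
  }
  df <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "volume_result"))
    tibble(pressure = pressures[i], v_cell = r$v_cell, v_net = r$v_net,
           v_void = r$v_void, sigma = r$sigma_net)
  }))
  df$Z <- Z
  pressure_series(df, id = id)
}

#' Scale a series to formula units
#'
#' Divides every volume (and `sigma`) by the per-record `Z` so that series
#' can be compared across phase transitions where the number of formula
#' units per cell changes. Idempotent: an already-scaled series is returned
#' unchanged.
#'
#' @param series A [pressure_series()].
#' @return The scaled series (attribute `scaled` set, `Z` reset to 1).
#' @export
scale_to_Z <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  if (isTRUE(attr(series, "scaled"))) return(series)
  if (anyNA(series$Z)) abort("Z missing: cannot scale")
  df <- as_tibble(series)
  z <- df$Z
  df$v_cell <- df$v_cell / z
  df$v_net <- df$v_net / z
  df$v_void <- df$v_void / z
  df$sigma <- df$sigma / z
  df$Z <- 1
  pressure_series(df, id = attr(series, "id"), scaled = TRUE)
}

#' Extract one volume component of a series
#'
#' @param series A [pressure_series()].
#' @param component `"net"`, `"void"` or `"cell"`.
#' @return A tibble `pressure`, `volume`, `sigma_v` ready for [fit_eos()].
#' @export
series_component <- function(series, component = c("net", "void", "cell")) {
  component <- match.arg(component)
  col <- paste0("v_", component)
  tibble(pressure = series$pressure, volume = series[[col]], sigma_v = series$sigma)
}

# small-sample corrected information criterion from a (weighted) RSS;
# k counts the fitted EoS parameters plus the residual variance, and for a
# two-segment model additionally the break position
aicc_from_rss <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

n_free_params <- function(family) switch(family, bm2 = 2L, bm3 = 3L, vinet = 3L)

#' Piecewise equation-of-state fit across a candidate transition
#'
#' Fits one EoS per segment of the series. With `candidate_breaks =
#' "scan"`, every midpoint between consecutive pressures that leaves both
#' segments at least `min_seg` points is tried; the break minimizing the
#' total weighted residual sum is retained only if it also beats the
#' single-segment fit on a small-sample information criterion (counting the
#' break position as a parameter). Otherwise a single-segment report is
#' returned. The per-molecule volume step at the break is the difference of
#' the two segment fits' predicted volumes at the break pressure.
#'
#' @param series A [pressure_series()].
#' @param component `"net"`, `"void"` or `"cell"`.
#' @param family EoS family for both segments.
#' @param candidate_breaks `"scan"` or a numeric vector of break pressures
#'   to evaluate.
#' @param min_seg Minimum points per segment (defaults to free parameters
#'   plus one).
#' @return An object of class `break_report`: `break_pressure` (`NA` when no
#'   break is supported), `fits` (list of one or two `eos_fit`s), `delta_v`
#'   (segment-1 minus segment-2 predicted volume at the break), `component`,
#'   `family` and the scan table `candidates`.
#' @export
piecewise_fit <- function(series, component = c("net", "void", "cell"),
                          family = c("bm2", "bm3", "vinet"),
                          candidate_breaks = "scan", min_seg = NULL) {
  stopifnot(inherits(series, "pressure_series"))
  component <- match.arg(component)
  family <- match.arg(tolower(family[1]), c("bm2", "bm3", "vinet"))
  df <- series_component(series, component)
  n <- nrow(df)
  npar <- n_free_params(family)
  min_seg <- min_seg %||% (npar + 1L)

  single <- fit_eos(df, family)
  rss_single <- sum(single$weights * single$residuals^2)
  aicc_single <- aicc_from_rss(rss_single, n, npar + 1L)

  p <- df$pressure
  cands <- if (identical(candidate_breaks, "scan")) {
    mids <- (p[-1] + p[-n]) / 2
    ok <- vapply(mids, function(b) sum(p < b) >= min_seg && sum(p > b) >= min_seg, logical(1))
    mids[ok]
  } else {
    as.numeric(candidate_breaks)
  }

  best <- NULL
  rows <- list()
  for (b in cands) {
    lo <- df[p < b, , drop = FALSE]
    hi <- df[p > b, , drop = FALSE]
    if (nrow(lo) < min_seg || nrow(hi) < min_seg) next
    two <- tryCatch(list(fit_eos(lo, family), fit_eos(hi, family)), error = function(e) NULL)
    if (is.null(two)) next
    rss <- sum(two[[1]]$weights * two[[1]]$residuals^2) +
      sum(two[[2]]$weights * two[[2]]$residuals^2)
    aicc <- aicc_from_rss(rss, n, 2L * npar + 2L)
    rows[[length(rows) + 1]] <- tibble(break_pressure = b, rss = rss, aicc = aicc)
    if (is.null(best) || rss < best$rss) {
      best <- list(b = b, fits = two, rss = rss, aicc = aicc)
    }
  }
  candidates <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(break_pressure = numeric(0), rss = numeric(0), aicc = numeric(0))
  }

  use_break <- !is.null(best) && best$aicc < aicc_single
  if (use_break) {
    v1 <- predict_eos_volume(best$fits[[1]], best$b)$volume
    v2 <- predict_eos_volume(best$fits[[2]], best$b)$volume
    report <- list(
      break_pressure = best$b, fits = best$fits, delta_v = v1 - v2,
      component = component, family = family,
      candidates = candidates, aicc_single = aicc_single, aicc_break = best$aicc,
      series = series
    )
  } else {
    report <- list(
      break_pressure = NA_real_, fits = list(single), delta_v = NA_real_,
      component = component, family = family,
      candidates = candidates, aicc_single = aicc_single,
      aicc_break = if (is.null(best)) NA_real_ else best$aicc,
      series = series
    )
  }
  class(report) <- "break_report"
  report
}

#' @export
print.break_report <- function(x, ...) {
  if (is.na(x$break_pressure)) {
    cat(sprintf("<break_report %s/%s> no break supported (single %s fit)\n",
                x$component, toupper(x$family), toupper(x$family)))
  } else {
    k1 <- x$fits[[1]]$params$estimate[2]
    k2 <- x$fits[[2]]$params$estimate[2]
    cat(sprintf(
      "<break_report %s/%s> break at %.3f GPa; K0 %.2f -> %.2f GPa; delta V = %.3f A^3\n",
      x$component, toupper(x$family), x$break_pressure, k1, k2, x$delta_v
    ))
  }
  invisible(x)
}

#' Flag premonitory deviations from an extrapolated EoS
#'
#' Fits the chosen family to a leading window of the series and compares
#' every later observation with the extrapolated volume. Points deviating by
#' more than `k_sigma` combined standard deviations (fit-prediction variance
#' and measurement sigma added in quadrature) are flagged, with the sign of
#' the deviation reported; systematic negative deviations at the top of a
#' pressure range are the premonitory signature preceding a transition or
#' loss of long-range order.
#'
#' @inheritParams piecewise_fit
#' @param fit_window Number of leading points to fit. Default: the points
#'   before the first scanned break if one is found, else 5.
#' @param k_sigma Flagging threshold in combined standard deviations.
#' @return A tibble of the trailing points: `index`, `pressure`, `observed`,
#'   `predicted`, `deviation`, `sigma_combined`, `sign`, `flagged`.
#' @export
premonitory_scan <- function(series, component = c("net", "void", "cell"),
                             family = c("bm3", "bm2", "vinet"),
                             fit_window = NULL, k_sigma = 3) {
  stopifnot(inherits(series, "pressure_series"))
  component <- match.arg(component)
  family <- match.arg(tolower(family[1]), c("bm2", "bm3", "vinet"))
  df <- series_component(series, component)
  n <- nrow(df)
  npar <- n_free_params(family)
  if (is.null(fit_window)) {
    br <- tryCatch(
      piecewise_fit(series, component, family)$break_pressure,
      error = function(e) NA_real_
    )
    fit_window <- if (is.finite(br)) sum(df$pressure < br) else 5L
  }
  if (fit_window < npar + 1) {
    abort(sprintf("fit window of %d points is below the %d-point floor for %s",
                  fit_window, npar + 1, family))
  }
  if (fit_window >= n) abort("fit window leaves no trailing points to scan")
  lead <- df[seq_len(fit_window), , drop = FALSE]
  fit <- fit_eos(lead, family)
  trail <- df[(fit_window + 1):n, , drop = FALSE]
  pred <- predict_eos_volume(fit, trail$pressure, se = TRUE)
  dev <- trail$volume - pred$volume
  sig <- sqrt(pred$sigma_volume^2 + trail$sigma_v^2)
  flagged <- abs(dev) > k_sigma * sig
  tibble(
    index = (fit_window + 1):n,
    pressure = trail$pressure,
    observed = trail$volume,
    predicted = pred$volume,
    deviation = dev,
    sigma_combined = sig,
    sign = sign(dev),
    flagged = flagged
  )
}
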