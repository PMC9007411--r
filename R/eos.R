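#' Equation-of-state pressure
#'
#' Standard isothermal pressure-volume relations used for network, void and
#' total volumes:
#'
#' * `bm3` (third-order Birch-Murnaghan):
#'   `P = (3 K0 / 2) [(V0/V)^(7/3) - (V0/V)^(5/3)] {1 + (3/4)(K' - 4)[(V0/V)^(2/3) - 1]}`
#' * `bm2`: the same with `K'` fixed at 4 (the bracketed correction vanishes)
#' * `vinet`: `P = 3 K0 (1 - f) f^-2 exp[(3/2)(K' - 1)(1 - f)]` with
#'   `f = (V/V0)^(1/3)`, generally better for very soft solids and strong
#'   compression - in this context, the void volumes.
#'
#' @param family One of `"bm2"`, `"bm3"`, `"vinet"`.
#' @param v Volume(s), cubic angstroms.
#' @param v0 Zero-pressure volume, cubic angstroms.
#' @param k0 Zero-pressure bulk modulus, GPa.
#' @param kprime Pressure derivative of the bulk modulus (dimensionless);
#'   ignored for `bm2`.
#' @return Pressure(s) in GPa.
#' @export
#' @examples
#' eos_pressure("bm2", 900, v0 = 1000, k0 = 10)  # 1.301 GPa
eos_pressure <- function(family, v, v0, k0, kprime = 4) {
  family <- match.arg(tolower(family), c("bm2", "bm3", "vinet"))
  if (any(v <= 0) || v0 <= 0 || k0 <= 0) abort("v, v0 and k0 must be positive")
  if (family == "bm2") kprime <- 4
  if (family %in% c("bm2", "bm3")) {
    eta <- (v0 / v)^(1 / 3)
    1.5 * k0 * (eta^7 - eta^5) * (1 + 0.75 * (kprime - 4) * (eta^2 - 1))
  } else {
    f <- (v / v0)^(1 / 3)
    3 * k0 * (1 - f) / f^2 * exp(1.5 * (kprime - 1) * (1 - f))
  }
}

#' Equation-of-state volume (inverse relation)
#'
#' Solves `P(V) = p` for `V` by bisection. All three families depend on
#' volume only through `V/V0`, so `V(P) = V0 h(P; K0, K')`.
#'
#' @inheritParams eos_pressure
#' @param p Pressure(s), GPa (non-negative).
#' @return Volume(s), cubic angstroms.
#' @export
eos_volume <- function(family, p, v0, k0, kprime = 4) {
  vapply(p, function(pi) {
    if (pi < 0) abort("pressure must be non-negative")
    if (pi == 0) return(v0)
    uniroot(
      function(v) eos_pressure(family, v, v0, k0, kprime) - pi,
      lower = v0 * 1e-3, upper = v0, tol = 1e-12 * v0
    )$root
  }, numeric(1))
}

# analytic K(P) = -V dP/dV evaluated via exact dP/dV of the closed forms
# (numerical derivative of eos_pressure at the inverted volume)
eos_bulk_modulus <- function(family, p, v0, k0, kprime = 4) {
  v <- eos_volume(family, p, v0, k0, kprime)
  h <- v * 1e-7
  dpdv <- (eos_pressure(family, v + h, v0, k0, kprime) -
    eos_pressure(family, v - h, v0, k0, kprime)) / (2 * h)
  -v * dpdv
}

#' Fit an equation of state to a pressure-volume series
#'
#' Weighted nonlinear least squares of the model pressure at the observed
#' volumes against the observed pressures (the convention of dedicated EoS
#' fitting programs). Weights are `1/sigma_p^2` when a `sigma_p` column is
#' present, otherwise the fit is unweighted. Parameter standard
#' uncertainties come from the fit covariance.
#'
#' @param series A data frame with columns `pressure` (GPa) and `volume`
#'   (cubic angstroms); optional `sigma_p` (GPa) for weighting.
#' @param family `"bm2"` (fits `v0`, `k0`), `"bm3"` or `"vinet"` (also
#'   `kprime`).
#' @param fix_v0 Optional fixed zero-pressure volume (not refined).
#' @param min_points Minimum number of points; defaults to the number of
#'   free parameters plus one.
#' @return An object of class `eos_fit`; see [tidy.eos_fit()] and
#'   [glance.eos_fit()].
#' @export
fit_eos <- function(series, family = c("bm3", "bm2", "vinet"),
                    fix_v0 = NULL, min_points = NULL) {
  family <- match.arg(tolower(family[1]), c("bm2", "bm3", "vinet"))
  df <- as_tibble(series)
  if (!all(c("pressure", "volume") %in% names(df))) {
    abort("series must have columns 'pressure' and 'volume'")
  }
  if (any(df$pressure < 0)) abort("pressures must be non-negative")
  n_free <- switch(family, bm2 = 2L, bm3 = 3L, vinet = 3L) - if (is.null(fix_v0)) 0L else 1L
  floor_pts <- min_points %||% (n_free + 1L)
  if (nrow(df) < max(floor_pts, n_free)) {
    abort(sprintf("too few points: %d observations for %d free parameters (floor %d)",
                  nrow(df), n_free, floor_pts))
  }
  w <- if ("sigma_p" %in% names(df) && all(is.finite(df$sigma_p)) && all(df$sigma_p > 0)) {
    1 / df$sigma_p^2
  } else rep(1, nrow(df))

  # robust starting values: v0 from the largest observed volume, k0 from a
  # secant of -V dP/dV across the series
  v0_start <- fix_v0 %||% (max(df$volume) * 1.02)
  o <- order(df$pressure)
  dv <- diff(df$volume[o]); dp <- diff(df$pressure[o])
  k0_start <- abs(mean(df$volume) * mean(dp / ifelse(dv == 0, -1e-6, dv)))
  if (!is.finite(k0_start) || k0_start <= 0) k0_start <- 10
  kp_start <- if (family == "vinet") 6 else 4

  fml <- switch(family,
    bm2 = if (is.null(fix_v0)) {
      pressure ~ eos_pressure("bm2", volume, v0, k0)
    } else pressure ~ eos_pressure("bm2", volume, fix_v0, k0),
    bm3 = if (is.null(fix_v0)) {
      pressure ~ eos_pressure("bm3", volume, v0, k0, kp)
    } else pressure ~ eos_pressure("bm3", volume, fix_v0, k0, kp),
    vinet = if (is.null(fix_v0)) {
      pressure ~ eos_pressure("vinet", volume, v0, k0, kp)
    } else pressure ~ eos_pressure("vinet", volume, fix_v0, k0, kp)
  )
  start <- list(k0 = k0_start)
  if (is.null(fix_v0)) start <- c(list(v0 = v0_start), start)
  if (family != "bm2") start <- c(start, list(kp = kp_start))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      fml, data = df, start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      abort(paste0("EoS fit failed (", family, "): ", conditionMessage(e),
                   "; start was ", paste(sprintf("%s=%.4g", names(start), unlist(start)), collapse = ", ")))
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"], error = function(e) rep(NA_real_, length(est)))
  params <- tibble(
    term = c("v0", "k0", "kprime"),
    estimate = c(
      if (is.null(fix_v0)) est[["v0"]] else fix_v0,
      est[["k0"]],
      if (family == "bm2") 4 else est[["kp"]]
    ),
    std.error = c(
      if (is.null(fix_v0)) se[["v0"]] else 0,
      se[["k0"]],
      if (family == "bm2") 0 else se[["kp"]]
    ),
    fixed = c(!is.null(fix_v0), FALSE, family == "bm2")
  )
  if (params$estimate[params$term == "k0"] <= 0) {
    abort("EoS fit failed: converged to non-positive k0")
  }
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  structure(
    list(
      family = family,
      params = params,
      fix_v0 = fix_v0,
      vcov = vc,
      data = df,
      weights = w,
      residuals = df$pressure - predict_pressure_params(family, df$volume, params),
      n_points = nrow(df)
    ),
    class = "eos_fit"
  )
}

predict_pressure_params <- function(family, v, params) {
  p <- setNames(params$estimate, params$term)
  eos_pressure(family, v, p[["v0"]], p[["k0"]], p[["kprime"]])
}

#' Predict volume at pressure from a fitted EoS
#'
#' @param fit An `eos_fit`.
#' @param pressure Pressures in GPa.
#' @param se Also return the propagated prediction standard error (first
#'   order through the parameter covariance).
#' @return A tibble with `pressure`, `volume` and (with `se = TRUE`)
#'   `sigma_volume`.
#' @export
predict_eos_volume <- function(fit, pressure, se = FALSE) {
  stopifnot(inherits(fit, "eos_fit"))
  p <- setNames(fit$params$estimate, fit$params$term)
  v <- eos_volume(fit$family, pressure, p[["v0"]], p[["k0"]], p[["kprime"]])
  out <- tibble(pressure = pressure, volume = v)
  if (se) {
    out$sigma_volume <- vapply(pressure, function(pi) {
      sqrt(max(0, volume_pred_var(fit, pi)))
    }, numeric(1))
  }
  out
}

# first-order variance of V(P; theta) through the fit covariance
volume_pred_var <- function(fit, pressure) {
  vc <- fit$vcov
  if (is.null(vc)) return(0)
  free <- colnames(vc)
  p <- setNames(fit$params$estimate, fit$params$term)
  base <- c(v0 = unname(p[["v0"]]), k0 = unname(p[["k0"]]), kp = unname(p[["kprime"]]))
  f <- function(th) {
    eos_volume(fit$family, pressure, th[["v0"]], th[["k0"]], th[["kp"]])
  }
  g <- vapply(free, function(nm) {
    h <- max(abs(base[[nm]]) * 1e-5, 1e-8)
    up <- base; up[[nm]] <- up[[nm]] + h
    dn <- base; dn[[nm]] <- dn[[nm]] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
  drop(t(g) %*% vc %*% g)
}

#' @export
print.eos_fit <- function(x, ...) {
  p <- setNames(x$params$estimate, x$params$term)
  s <- setNames(x$params$std.error, x$params$term)
  cat(sprintf(
    "<eos_fit %s> V0=%.3f(%.3f) A^3  K0=%.3f(%.3f) GPa  K'=%.3f(%.3f)  n=%d  rms(P)=%.4g GPa\n",
    toupper(x$family), p[["v0"]], s[["v0"]], p[["k0"]], s[["k0"]],
    p[["kprime"]], s[["kprime"]], x$n_points, sqrt(mean(x$residuals^2))
  ))
  invisible(x)
}

#' Numeric bulk modulus from a pressure-volume series
#'
#' `K = -V (dP/dV)` evaluated at interior points by three-point Lagrange
#' central differences (exact for locally quadratic `P(V)`, second-order
#' accurate on smooth series). Serves as the model-free fallback for
#' segments that no standard EoS form fits, e.g. immediately after a phase
#' transition.
#'
#' @param series Data frame with columns `pressure` and `volume`; `volume`
#'   must be strictly monotone in `pressure`.
#' @return A tibble `pressure`, `k` (GPa) at the interior points.
#' @export
numeric_bulk_modulus <- function(series) {
  df <- as_tibble(series)
  if (nrow(df) < 3) abort("need at least 3 points")
  o <- order(df$pressure)
  v <- df$volume[o]; p <- df$pressure[o]
  dv <- diff(v)
  if (!(all(dv < 0) || all(dv > 0))) {
    bad <- which(sign(dv) != sign(dv[1])) + 1
    abort(paste0("volume is not strictly monotone in pressure at index(es): ",
                 paste(o[bad], collapse = ", ")))
  }
  i <- 2:(length(v) - 1)
  # derivative of the quadratic through (v[i-1], v[i], v[i+1]) at v[i]
  h1 <- v[i] - v[i - 1]
  h2 <- v[i + 1] - v[i]
  dpdv <- -h2 / (h1 * (h1 + h2)) * p[i - 1] +
    (h2 - h1) / (h1 * h2) * p[i] +
    h1 / (h2 * (h1 + h2)) * p[i + 1]
  tibble(pressure = p[i], k = -v[i] * dpdv)
}

#' Compose the overall bulk modulus from component moduli
#'
#' Because the total volume is the sum of the network and void volumes, the
#' overall compressibility is the volume-fraction-weighted sum of the
#' component compressibilities, giving the reciprocal-mixing relation
#' `1/K = x/K_net + (1 - x)/K_void` where `x` is the packing coefficient.
#'
#' @param k_net,k_void Component bulk moduli, GPa (positive).
#' @param x Packing coefficient, strictly inside (0, 1).
#' @return Overall bulk modulus in GPa.
#' @export
#' @examples
#' compose_bulk_modulus(100, 3.2, 0.75)  # 11.7 GPa
compose_bulk_modulus <- function(k_net, k_void, x) {
  if (any(k_net <= 0) || any(k_void <= 0)) abort("component moduli must be positive")
  if (any(x <= 0) || any(x >= 1)) abort("packing coefficient must lie strictly in (0, 1)")
  1 / (x / k_net + (1 - x) / k_void)
}

#' Error propagation through the bulk-modulus partition
#'
#' Propagates uncertainties of the component moduli into the composed
#' overall bulk modulus, either analytically (first-order partial
#' derivatives of the reciprocal-mixing relation) or by Gaussian Monte
#' Carlo draws.
#'
#' @inheritParams compose_bulk_modulus
#' @param sigma_net,sigma_void Standard uncertainties of the component
#'   moduli, GPa (non-negative).
#' @param method `"analytic"` or `"montecarlo"`.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Optional seed for the Monte Carlo method.
#' @return A tibble: `k_overall`, `sigma_k`, `rel_err_k` and the component
#'   relative errors `rel_err_net`, `rel_err_void` (all relative errors as
#'   fractions).
#' @export
propagate_partition_error <- function(k_net, sigma_net, k_void, sigma_void, x,
                                      method = c("analytic", "montecarlo"),
                                      n_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (sigma_net < 0 || sigma_void < 0) abort("sigmas must be non-negative")
  k <- compose_bulk_modulus(k_net, k_void, x)
  if (method == "analytic") {
    dk_dnet <- k^2 * x / k_net^2
    dk_dvoid <- k^2 * (1 - x) / k_void^2
    sigma_k <- sqrt((dk_dnet * sigma_net)^2 + (dk_dvoid * sigma_void)^2)
  } else {
    if (!is.null(seed)) {
      seeds <- derive_seeds(seed, 1)
      set.seed(seeds[1])
    }
    kn <- rnorm(n_draws, k_net, sigma_net)
    kv <- rnorm(n_draws, k_void, sigma_void)
    ok <- kn > 0 & kv > 0
    sigma_k <- sd(1 / (x / kn[ok] + (1 - x) / kv[ok]))
  }
  tibble(
    k_overall = k, sigma_k = sigma_k, rel_err_k = sigma_k / k,
    rel_err_net = sigma_net / k_net, rel_err_void = sigma_void / k_void,
    method = method
  )
}
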