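#' Two-state thermal transition model
#'
#' Fraction of molecules in the high-exchanging (activated) state as a
#' function of absolute temperature:
#' `F(T) = f0 + (fmax - f0) * exp(x) / (1 + exp(x))` with
#' `x = (T - Tm) * dH / (R * T * Tm)`. `dH` is an apparent steepness
#' parameter, not an equilibrium unfolding enthalpy: the transition it
#' describes is kinetically controlled and irreversible, so the fit is used
#' only to locate the temperature of half-maximal conversion.
#'
#' @param T_K absolute temperature(s) in Kelvin (> 0)
#' @param f0,fmax plateau values at low and high temperature (either
#'   orientation; `fmax < f0` describes a falling transition)
#' @param Tm_K transition midpoint in Kelvin
#' @param dH apparent steepness parameter in J/mol
#' @return fraction(s); numerically stable for extreme arguments
#' @export
thermal_model <- function(T_K, f0, fmax, Tm_K, dH) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be > 0 K", call. = FALSE)
  assert_finite_scalar(dH, "dH")
  x <- (T_K - Tm_K) * dH / (GAS_CONSTANT * T_K * Tm_K)
  f0 + (fmax - f0) * stats::plogis(x)
}

#' Fit the thermal transition to fraction-vs-temperature data
#'
#' Least-squares fit of [thermal_model()]. Temperatures are taken in degrees
#' Celsius at the interface and converted to Kelvin internally. Either
#' plateau can be fixed (e.g. `f0_fixed = 0`, `fmax_fixed = 100` on
#' percent-scale data). Points with standard errors are weighted by
#' `1 / se^2`; otherwise the fit is unweighted. Falling transitions are
#' handled by letting `fmax < f0` rather than re-orienting the data.
#'
#' @param temperature_C temperatures in degrees Celsius
#' @param fraction observed fractions (0-1, or 0-100 with
#'   `scale = "percent"`)
#' @param se optional standard errors for weighting
#' @param f0_fixed,fmax_fixed optionally fix a plateau
#' @param scale `"fraction"` or `"percent"`; recorded in the result and used
#'   for plausibility checks only (the model is scale-equivariant)
#' @return an object of class `transition_fit`: `Tm_C`, `dH_apparent` (J/mol),
#'   `f0`, `fmax`, standard errors, an extrapolation flag when the midpoint
#'   falls outside the sampled range, and the convergence flag
#' @export
fit_thermal_transition <- function(temperature_C, fraction, se = NULL,
                                   f0_fixed = NULL, fmax_fixed = NULL,
                                   scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  assert_finite_vector(temperature_C, "temperature_C")
  assert_finite_vector(fraction, "fraction")
  stopifnot(length(temperature_C) == length(fraction))
  n_distinct <- length(unique(temperature_C))
  both_fixed <- !is.null(f0_fixed) && !is.null(fmax_fixed)
  if (n_distinct < ifelse(both_fixed, 2L, 4L))
    stop("need at least ", ifelse(both_fixed, 2L, 4L),
         " distinct temperatures", call. = FALSE)
  if (stats::sd(fraction) == 0)
    stop("all fractions identical: no transition to fit", call. = FALSE)
  w <- if (!is.null(se)) {
    assert_finite_vector(se, "se")
    if (any(se <= 0)) stop("standard errors must be > 0", call. = FALSE)
    1 / se^2
  } else rep(1, length(fraction))

  TK <- celsius_to_kelvin(temperature_C)
  ord <- order(TK)
  # initialization: plateaus from the temperature extremes, Tm at the point
  # closest to the half-range crossing, steepness 3e5 J/mol
  f_lo <- mean(fraction[temperature_C == min(temperature_C)])
  f_hi <- mean(fraction[temperature_C == max(temperature_C)])
  half <- (min(fraction) + max(fraction)) / 2
  Tm0 <- TK[which.min(abs(fraction - half))]
  p_names <- c("Tm", "dH",
               if (is.null(f0_fixed)) "f0", if (is.null(fmax_fixed)) "fmax")
  p0 <- c(Tm = Tm0, dH = 3e5,
          if (is.null(f0_fixed)) c(f0 = f_lo),
          if (is.null(fmax_fixed)) c(fmax = f_hi))
  model_of <- function(p) {
    f0 <- if (is.null(f0_fixed)) p[["f0"]] else f0_fixed
    fmax <- if (is.null(fmax_fixed)) p[["fmax"]] else fmax_fixed
    thermal_model(TK, f0, fmax, p[["Tm"]], p[["dH"]])
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) sqrt(w) * (fraction - model_of(p)),
    lower = c(1, -Inf, rep(-Inf, length(p0) - 2L)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  p <- fit$par
  covm <- tryCatch({
    dof <- max(length(fraction) - length(p), 1L)
    s2 <- fit$deviance / dof
    s2 * solve(as.matrix(fit$hessian))
  }, error = function(e) matrix(NA_real_, length(p), length(p)))
  ses <- sqrt(pmax(diag(covm), 0))
  names(ses) <- names(p)
  rng <- range(temperature_C)
  Tm_C <- kelvin_to_celsius(p[["Tm"]])
  structure(
    list(Tm_C = Tm_C, dH_apparent = p[["dH"]],
         f0 = if (is.null(f0_fixed)) p[["f0"]] else f0_fixed,
         fmax = if (is.null(fmax_fixed)) p[["fmax"]] else fmax_fixed,
         se_Tm_C = unname(ses["Tm"]), se_dH = unname(ses["dH"]),
         se_f0 = if (is.null(f0_fixed)) unname(ses["f0"]) else 0,
         se_fmax = if (is.null(fmax_fixed)) unname(ses["fmax"]) else 0,
         scale = scale, converged = fit$info %in% 1:3,
         extrapolated = Tm_C < rng[1] - 10 || Tm_C > rng[2] + 10,
         outside_sampled_range = Tm_C < rng[1] || Tm_C > rng[2],
         deviance = fit$deviance,
         note = "dH is an apparent steepness parameter, not an unfolding enthalpy"),
    class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(
    "<transition_fit> Tm = %.2f +/- %.2f C; apparent dH = %.3g J/mol; plateaus %.3g -> %.3g (%s)\n",
    x$Tm_C, x$se_Tm_C, x$dH_apparent, x$f0, x$fmax,
    if (x$converged) "converged" else "NOT CONVERGED"))
  if (x$outside_sampled_range)
    cat("  warning: midpoint outside the sampled temperature range\n")
  invisible(x)
}

#' Fit single-exponential exchange kinetics
#'
#' Fits `f(t) = f_end + (f_start - f_end) * exp(-k * t)` to
#' fraction-vs-time data; the orientation (rising or falling) is inferred
#' from the data. The rate is initialized by a coarse grid over `log k`
#' with the plateaus solved linearly at each candidate rate, then refined by
#' Levenberg-Marquardt.
#'
#' @param time_s times in seconds (>= 4 points)
#' @param fraction observed fractions
#' @param se optional standard errors for `1/se^2` weighting
#' @return an object of class `kinetic_fit`: `k_per_s`, `f_start`, `f_end`,
#'   standard errors, convergence flag
#' @export
fit_kinetics <- function(time_s, fraction, se = NULL) {
  assert_finite_vector(time_s, "time_s")
  assert_finite_vector(fraction, "fraction")
  stopifnot(length(time_s) == length(fraction))
  if (length(unique(time_s)) < 4L)
    stop("need at least 4 distinct time points", call. = FALSE)
  if (stats::sd(fraction) == 0)
    stop("all fractions identical: no decay to fit", call. = FALSE)
  w <- if (!is.null(se)) 1 / se^2 else rep(1, length(fraction))

  # coarse log-grid on k; plateaus are linear given k
  kgrid <- 10^seq(log10(0.1 / max(time_s)), log10(10 / min(time_s[time_s > 0])),
                  length.out = 40)
  sse_of <- function(k) {
    X <- cbind(1, exp(-k * time_s))
    co <- tryCatch(stats::lm.wfit(X, fraction, w)$coefficients,
                   error = function(e) c(NA, NA))
    if (any(!is.finite(co))) return(Inf)
    sum(w * (fraction - X %*% co)^2)
  }
  k0 <- kgrid[which.min(vapply(kgrid, sse_of, numeric(1)))]
  X0 <- cbind(1, exp(-k0 * time_s))
  co0 <- stats::lm.wfit(X0, fraction, w)$coefficients
  p0 <- c(k = k0, f_end = co0[[1]], amp = co0[[2]])  # amp = f_start - f_end
  fit <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) sqrt(w) *
      (fraction - (p[["f_end"]] + p[["amp"]] * exp(-p[["k"]] * time_s))),
    lower = c(1e-12, -Inf, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- fit$par
  covm <- tryCatch({
    dof <- max(length(fraction) - 3L, 1L)
    (fit$deviance / dof) * solve(as.matrix(fit$hessian))
  }, error = function(e) matrix(NA_real_, 3, 3))
  ses <- sqrt(pmax(diag(covm), 0))
  k_hat <- p[["k"]]
  converged <- fit$info %in% 1:3 && k_hat > 1e-12
  # se of f_start = f_end + amp via delta method
  se_fstart <- if (all(is.finite(covm)))
    sqrt(max(covm[2, 2] + covm[3, 3] + 2 * covm[2, 3], 0)) else NA_real_
  structure(list(k_per_s = k_hat, f_start = p[["f_end"]] + p[["amp"]],
                 f_end = p[["f_end"]],
                 se_k = ses[[1]], se_f_end = ses[[2]], se_f_start = se_fstart,
                 converged = converged, deviance = fit$deviance),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> k = %.4g +/- %.2g 1/s; f %.3g -> %.3g (%s)\n",
              x$k_per_s, x$se_k, x$f_start, x$f_end,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Arrhenius regression of rate constants
#'
#' Ordinary least squares of `ln k` on `1/T`; the activation energy is
#' `Ea = -slope * R`. For two points this reduces exactly to
#' `Ea = R * T1 * T2 / (T2 - T1) * ln(k2 / k1)`.
#'
#' @param temperature_K absolute temperatures in Kelvin (>= 2 distinct)
#' @param k_per_s rate constants (> 0)
#' @return an object of class `arrhenius_fit`: `Ea_J_mol`, `se_Ea_J_mol`,
#'   `ln_prefactor`, the stored slope, and the (T, k) points
#' @export
arrhenius_fit <- function(temperature_K, k_per_s) {
  assert_finite_vector(temperature_K, "temperature_K", positive = TRUE)
  assert_finite_vector(k_per_s, "k_per_s")
  stopifnot(length(temperature_K) == length(k_per_s))
  if (any(k_per_s <= 0))
    stop("all rate constants must be > 0", call. = FALSE)
  if (length(unique(temperature_K)) < 2L)
    stop("need at least 2 distinct temperatures", call. = FALSE)
  x <- 1 / temperature_K
  y <- log(k_per_s)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  se_slope <- if (length(y) > 2L)
    unname(sqrt(diag(stats::vcov(fit)))[2]) else NA_real_
  structure(list(Ea_J_mol = -slope * GAS_CONSTANT,
                 se_Ea_J_mol = if (is.na(se_slope)) NA_real_
                               else se_slope * GAS_CONSTANT,
                 ln_prefactor = unname(stats::coef(fit)[1]),
                 slope = slope,
                 points = data.frame(temperature_K = temperature_K,
                                     k_per_s = k_per_s)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.1f kJ/mol (%d rates)\n",
              x$Ea_J_mol / 1000, nrow(x$points)))
  invisible(x)
}
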