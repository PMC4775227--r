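#' Quadratic solution of the two-species binding equilibrium
#'
#' Exact fraction of DNA bound for `P + D <=> PD` with dissociation constant
#' `K`: the smaller root of the mass-action quadratic,
#' `fb = ((P + D + K) - sqrt((P + D + K)^2 - 4 P D)) / (2 D)`,
#' evaluated in the numerically stable conjugate form
#' `fb = 2 P / (P + D + K + sqrt((P + D + K)^2 - 4 P D))`, which also yields
#' the hyperbolic limit `P / (P + K)` as `D -> 0`. When the protein has only
#' a fraction `a` of binding-competent (active) molecules, pass
#' `p_active = a * p_total`.
#'
#' @param p_active_nM active protein (trimer) concentration, nM (>= 0)
#' @param dna_nM total DNA concentration, nM (>= 0)
#' @param kd_nM dissociation constant, nM (> 0)
#' @return fraction of DNA bound, in \[0, 1\]; monotone non-decreasing in
#'   `p_active_nM`
#' @export
bound_fraction_quadratic <- function(p_active_nM, dna_nM, kd_nM) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0))
    stop("kd_nM must be > 0", call. = FALSE)
  if (any(p_active_nM < 0) || any(dna_nM < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  s <- p_active_nM + dna_nM + kd_nM
  disc <- pmax(s^2 - 4 * p_active_nM * dna_nM, 0)
  fb <- 2 * p_active_nM / (s + sqrt(disc))
  pmin(pmax(fb, 0), 1)
}

#' Global fit of anisotropy titrations with fractional activity
#'
#' Fits all dilution series jointly with one shared dissociation constant and
#' shared anisotropy bounds, and one active fraction per condition:
#' `r = r_min + (r_max - r_min) * fb(a_c * trimer, dna, Kd)`.
#' Sharing `Kd`, `r_min` and `r_max` assumes all binding-competent trimers
#' bind the probe identically regardless of how they were formed; the active
#' fraction `a_c` is constant along a dilution series because trimers do not
#' dissociate upon dilution (an explicit model assumption recorded in the
#' result).
#'
#' @param data data frame with columns `condition`, `trimer_nM` (theoretical
#'   trimer concentration, i.e. monomer concentration / 3, tracked through
#'   the dilution series) and `anisotropy`; an [simulate_anisotropy()] result
#'   is accepted directly
#' @param dna_nM labelled DNA concentration (nM)
#' @return an object of class `binding_fit`: `kd_nM`, `r_min`, `r_max`,
#'   per-condition `active_fraction` with standard errors, bound-hit flags,
#'   convergence flag
#' @export
fit_anisotropy_global <- function(data, dna_nM = 10) {
  if (inherits(data, "anisotropy_dataset")) data <- data$data
  stopifnot(is.data.frame(data),
            all(c("condition", "trimer_nM", "anisotropy") %in% names(data)))
  if (any(data$trimer_nM <= 0))
    stop("trimer_nM must be > 0", call. = FALSE)
  conds <- unique(as.character(data$condition))
  if (min(table(data$condition)) < 4L)
    stop("need at least 4 points per condition", call. = FALSE)
  if (stats::sd(data$anisotropy) < 1e-12)
    stop("anisotropy shows no variation: nothing to fit", call. = FALSE)
  ci <- match(as.character(data$condition), conds)
  nc <- length(conds)

  r_lo <- min(data$anisotropy); r_hi <- max(data$anisotropy)
  # parameters: log(kd), r_min, dr (> 0), then one active fraction per
  # condition; log-kd keeps the problem well scaled across decades
  resid_fun <- function(p) {
    kd <- exp(p[[1]]); rmin <- p[[2]]; dr <- p[[3]]
    a <- p[3L + seq_len(nc)]
    fb <- bound_fraction_quadratic(a[ci] * data$trimer_nM, dna_nM, kd)
    data$anisotropy - (rmin + dr * fb)
  }
  lower <- c(log(1e-6), -Inf, 1e-9, rep(0, nc))
  upper <- c(log(1e9), Inf, Inf, rep(1, nc))
  # initialize each active fraction from the titration midpoint of its
  # dilution series: at half-maximal anisotropy, a * trimer ~ dna/2 + kd
  a_init <- function(kd0) {
    vapply(conds, function(cd) {
      d <- data[data$condition == cd, ]
      d <- d[order(d$trimer_nM), ]
      half <- r_lo + 0.5 * (r_hi - r_lo)
      if (max(d$anisotropy) < r_lo + 0.25 * (r_hi - r_lo)) return(0.02)
      i <- which(d$anisotropy >= half)[1]
      if (is.na(i)) return(1)
      p_mid <- d$trimer_nM[max(i, 1L)]
      min(max((dna_nM / 2 + kd0) / p_mid, 0.01), 1)
    }, numeric(1))
  }
  starts <- lapply(c(0.03, 0.1, 0.3, 1, 10) * dna_nM, function(kd0)
    c(log(kd0), r_lo, max(r_hi - r_lo, 1e-3), a_init(kd0)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("global anisotropy fit failed", call. = FALSE)
  p <- best$par
  p[[1]] <- exp(p[[1]])                      # back to kd scale
  np <- length(p)
  covm <- tryCatch({
    dof <- max(nrow(data) - np, 1L)
    (best$deviance / dof) * solve(as.matrix(best$hessian))
  }, error = function(e) matrix(NA_real_, np, np))
  ses <- sqrt(pmax(diag(covm), 0))
  a_hat <- p[3L + seq_len(nc)]
  at_bound <- a_hat < 1e-6 | a_hat > 1 - 1e-6
  se_a <- ses[3L + seq_len(nc)]
  se_a[at_bound] <- NA_real_          # curvature-based SE invalid at a bound
  structure(
    list(kd_nM = p[[1]], r_min = p[[2]], r_max = p[[2]] + p[[3]],
         se_kd_nM = p[[1]] * ses[[1]],      # delta method from log scale
         se_r_min = ses[[2]],
         se_r_max = sqrt(max(covm[2, 2] + covm[3, 3] + 2 * covm[2, 3], 0)),
         active_fraction = stats::setNames(a_hat, conds),
         se_active_fraction = stats::setNames(se_a, conds),
         at_bound = stats::setNames(at_bound, conds),
         dna_nM = dna_nM, converged = best$info %in% 1:3,
         deviance = best$deviance,
         assumptions = c(
           "shared Kd, r_min, r_max across all conditions",
           "active fraction constant along each dilution series (trimers do not dissociate on dilution)",
           "theoretical trimer concentration = monomer concentration / 3")),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Kd = %.3g +/- %.2g nM; r in [%.4f, %.4f] (%s)\n",
              x$kd_nM, x$se_kd_nM, x$r_min, x$r_max,
              if (x$converged) "converged" else "NOT CONVERGED"))
  print(round(x$active_fraction, 4))
  invisible(x)
}

#' Active-fraction surface over temperature and concentration
#'
#' Collects the per-condition active fractions of one or more global binding
#' fits (replicates) into a tidy table of DNA-binding-competent fraction
#' versus pre-incubation temperature and concentration, aggregated to mean
#' and SEM across replicates. This table feeds [fit_thermal_transition()] to
#' produce concentration-resolved transition midpoints.
#'
#' @param fits a [fit_anisotropy_global()] result or a list of them (one per
#'   replicate)
#' @param conditions data frame mapping condition labels to covariates:
#'   columns `label`, `temperature_C`, `preincubation_nM`
#' @return data frame: `temperature_C`, `preincubation_nM`,
#'   `active_fraction`, `sem`, `n`
#' @export
fraction_active_surface <- function(fits, conditions) {
  if (inherits(fits, "binding_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "binding_fit")),
            is.data.frame(conditions),
            all(c("label", "temperature_C", "preincubation_nM") %in%
                  names(conditions)))
  long <- do.call(rbind, lapply(seq_along(fits), function(i) {
    a <- fits[[i]]$active_fraction
    data.frame(label = names(a), active_fraction = unname(a), replicate = i)
  }))
  miss <- setdiff(long$label, conditions$label)
  if (length(miss))
    stop("conditions table missing label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- merge(long, conditions, by = "label")
  out <- do.call(rbind, lapply(
    split(m, list(m$temperature_C, m$preincubation_nM), drop = TRUE),
    function(d) data.frame(
      temperature_C = d$temperature_C[1],
      preincubation_nM = d$preincubation_nM[1],
      active_fraction = mean(d$active_fraction),
      sem = if (nrow(d) > 1)
        stats::sd(d$active_fraction) / sqrt(nrow(d)) else 0,
      n = nrow(d))))
  out <- out[order(out$preincubation_nM, out$temperature_C), ]
  rownames(out) <- NULL
  out
}
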