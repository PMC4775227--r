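#' Monomer-dimer mass-action equilibrium
#'
#' Quadratic solution of `2 M <=> D` with dissociation constant
#' `K = [M]^2 / [D]` (monomer-unit concentrations): for total concentration
#' `c` (in monomer units), `[M] = K * (sqrt(1 + 8 c / K) - 1) / 4`, evaluated
#' in the cancellation-free form `[M] = 2 c / (sqrt(1 + 8 c / K) + 1)`.
#' Conservation `[M] + 2 [D] = c` holds exactly. The dimer fraction is the
#' fraction of monomer units in dimers, `2 [D] / c`, which equals 1/2 exactly
#' at `c = K`; the fraction of molecules that are dimers,
#' `[D] / ([M] + [D])`, is available as an alternative convention.
#'
#' @param c_total_nM total protein concentration in monomer units (nM, >= 0)
#' @param kd_dim_nM monomer-dimer dissociation constant (nM, > 0)
#' @param convention `"units"` (fraction of monomer units in dimers, default)
#'   or `"molecules"` (fraction of molecules that are dimers) for the
#'   reported fraction
#' @return list of vectors: `monomer_nM`, `dimer_nM`, `fraction_dimer`
#'   (0 at `c_total = 0` by continuity)
#' @export
monomer_dimer_fraction <- function(c_total_nM, kd_dim_nM,
                                   convention = c("units", "molecules")) {
  convention <- match.arg(convention)
  if (any(!is.finite(kd_dim_nM)) || any(kd_dim_nM <= 0))
    stop("kd_dim_nM must be > 0", call. = FALSE)
  if (any(c_total_nM < 0))
    stop("c_total_nM must be >= 0", call. = FALSE)
  m <- 2 * c_total_nM / (sqrt(1 + 8 * c_total_nM / kd_dim_nM) + 1)
  d <- m^2 / kd_dim_nM
  fr <- ifelse(c_total_nM > 0,
               if (convention == "units") 2 * d / c_total_nM
               else d / (m + d),
               0)
  list(monomer_nM = m, dimer_nM = d, fraction_dimer = fr)
}

#' Construct a monomer-dimer setpoint model
#'
#' Links total protein concentration to the thermal transition midpoint by
#' assuming the dimer fraction determines Tm: dilute protein behaves like
#' monomer (midpoint `tm_monomer_C`), concentrated protein like dimer
#' (`tm_dimer_C < tm_monomer_C`), so higher concentration lowers the
#' activation setpoint.
#'
#' @param kd_dim_nM monomer-dimer dissociation constant, `[M]^2/[D]` in
#'   monomer-unit nM
#' @param tm_monomer_C transition midpoint of the monomer (degrees C)
#' @param tm_dimer_C transition midpoint of the dimer (degrees C); must be
#'   below `tm_monomer_C`
#' @return an object of class `dimer_model`
#' @export
dimer_model <- function(kd_dim_nM = 330, tm_monomer_C = 53, tm_dimer_C = 33) {
  assert_finite_scalar(kd_dim_nM, "kd_dim_nM", positive = TRUE)
  assert_finite_scalar(tm_monomer_C, "tm_monomer_C")
  assert_finite_scalar(tm_dimer_C, "tm_dimer_C")
  if (tm_dimer_C >= tm_monomer_C)
    stop("field 'tm_dimer_C' must be below tm_monomer_C", call. = FALSE)
  structure(list(kd_dim_nM = kd_dim_nM, tm_monomer_C = tm_monomer_C,
                 tm_dimer_C = tm_dimer_C), class = "dimer_model")
}

#' @export
print.dimer_model <- function(x, ...) {
  cat(sprintf("<dimer_model> Kd = %.3g nM; Tm,M = %.2f C; Tm,D = %.2f C\n",
              x$kd_dim_nM, x$tm_monomer_C, x$tm_dimer_C))
  invisible(x)
}

#' Transition midpoint as a function of concentration
#'
#' `Tm(c) = Tm,M + fraction_dimer(c) * (Tm,D - Tm,M)`: bounded between the
#' dimer and monomer midpoints and monotone non-increasing in concentration
#' when `Tm,D < Tm,M`.
#'
#' @param c_total_nM total concentration(s), monomer units (nM)
#' @param model a [dimer_model()]
#' @param convention dimer-fraction convention, see
#'   [monomer_dimer_fraction()]
#' @return Tm in degrees Celsius
#' @export
tm_of_concentration <- function(c_total_nM, model,
                                convention = c("units", "molecules")) {
  stopifnot(inherits(model, "dimer_model"))
  fr <- monomer_dimer_fraction(c_total_nM, model$kd_dim_nM,
                               convention = convention)$fraction_dimer
  model$tm_monomer_C + fr * (model$tm_dimer_C - model$tm_monomer_C)
}

#' Fit the monomer-dimer setpoint model to (concentration, Tm) data
#'
#' Unweighted least squares of [tm_of_concentration()]. Because the fit is
#' most sensitive to points at concentrations below the dissociation
#' constant, a caveat flag is raised when no data point lies below
#' `Kd / 3`; when the sampled concentrations leave the transition region
#' entirely (every point more than 90 percent dimer, or every point less
#' than 10 percent), the dissociation constant is flagged unidentifiable.
#'
#' @param concentration_nM total concentrations (monomer units, nM, >= 3
#'   distinct)
#' @param Tm_C observed transition midpoints (degrees C)
#' @param convention dimer-fraction convention, see
#'   [monomer_dimer_fraction()]
#' @return an object of class `dimer_model_fit`: the fitted [dimer_model()]
#'   plus standard errors and flags (`low_conc_caveat`, `kd_unidentifiable`,
#'   `converged`)
#' @export
fit_dimer_model <- function(concentration_nM, Tm_C,
                            convention = c("units", "molecules")) {
  convention <- match.arg(convention)
  assert_finite_vector(concentration_nM, "concentration_nM", positive = TRUE)
  assert_finite_vector(Tm_C, "Tm_C")
  stopifnot(length(concentration_nM) == length(Tm_C))
  if (length(unique(concentration_nM)) < 3L)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  if (stats::sd(Tm_C) < 1e-9)
    stop("Tm values are flat: no concentration dependence to fit",
         call. = FALSE)
  p0 <- c(kd = stats::median(concentration_nM),
          tmM = max(Tm_C), tmD = min(Tm_C))
  resid_fun <- function(p) {
    fr <- monomer_dimer_fraction(concentration_nM, p[["kd"]],
                                 convention = convention)$fraction_dimer
    Tm_C - (p[["tmM"]] + fr * (p[["tmD"]] - p[["tmM"]]))
  }
  starts <- list(p0,
                 c(kd = min(concentration_nM), tmM = max(Tm_C) + 2,
                   tmD = min(Tm_C) - 2),
                 c(kd = max(concentration_nM), tmM = max(Tm_C),
                   tmD = min(Tm_C)))
  best <- NULL
  for (ps in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = ps, lower = c(1e-9, -Inf, -Inf),
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("dimer model fit failed", call. = FALSE)
  p <- best$par
  covm <- tryCatch({
    dof <- max(length(Tm_C) - 3L, 1L)
    (best$deviance / dof) * solve(as.matrix(best$hessian))
  }, error = function(e) matrix(NA_real_, 3, 3))
  ses <- sqrt(pmax(diag(covm), 0))
  fr <- monomer_dimer_fraction(concentration_nM, p[["kd"]],
                               convention = convention)$fraction_dimer
  structure(
    list(kd_dim_nM = p[["kd"]], tm_monomer_C = p[["tmM"]],
         tm_dimer_C = p[["tmD"]],
         se_kd_dim_nM = ses[[1]], se_tm_monomer_C = ses[[2]],
         se_tm_dimer_C = ses[[3]],
         convention = convention,
         low_conc_caveat = min(concentration_nM) > p[["kd"]] / 3,
         kd_unidentifiable = all(fr > 0.9) || all(fr < 0.1),
         converged = best$info %in% 1:3, deviance = best$deviance),
    class = "dimer_model_fit")
}

#' @export
print.dimer_model_fit <- function(x, ...) {
  cat(sprintf(
    "<dimer_model_fit> Kd = %.3g +/- %.2g nM; Tm,M = %.2f C; Tm,D = %.2f C (%s)\n",
    x$kd_dim_nM, x$se_kd_dim_nM, x$tm_monomer_C, x$tm_dimer_C,
    if (x$converged) "converged" else "NOT CONVERGED"))
  if (x$low_conc_caveat)
    cat("  caveat: no data below Kd/3; estimates are sensitive to low-concentration points\n")
  if (x$kd_unidentifiable)
    cat("  warning: sampled concentrations miss the transition region; Kd unidentifiable\n")
  invisible(x)
}

#' Extract the fitted model from a dimer_model_fit
#'
#' @param fit a [fit_dimer_model()] result
#' @return a [dimer_model()]
#' @export
as_dimer_model <- function(fit) {
  stopifnot(inherits(fit, "dimer_model_fit"))
  dimer_model(fit$kd_dim_nM, fit$tm_monomer_C, fit$tm_dimer_C)
}

#' Simulate Tm-vs-concentration curves for model variants
#'
#' Evaluates [tm_of_concentration()] over a concentration grid for the base
#' model and a set of parameter overrides — e.g. a lowered dimerization Kd,
#' or a lowered Kd together with a lowered dimer Tm, to emulate the effect of
#' a chaperone such as Hsp90 on the setpoint.
#'
#' @param base a [dimer_model()]
#' @param variants named list of override lists, each containing any of
#'   `kd_dim_nM`, `tm_monomer_C`, `tm_dimer_C`
#' @param c_grid concentration grid (nM)
#' @return long data frame: `variant`, `concentration_nM`, `Tm_C`
#' @export
simulate_variants <- function(base, variants = list(),
                              c_grid = 10^seq(1, log10(5000), length.out = 60)) {
  stopifnot(inherits(base, "dimer_model"))
  models <- c(list(base = base), lapply(variants, function(ov) {
    stopifnot(is.list(ov),
              all(names(ov) %in% c("kd_dim_nM", "tm_monomer_C", "tm_dimer_C")))
    m <- utils::modifyList(unclass(base), ov)
    dimer_model(m$kd_dim_nM, m$tm_monomer_C, m$tm_dimer_C)
  }))
  do.call(rbind, lapply(names(models), function(nm)
    data.frame(variant = nm, concentration_nM = c_grid,
               Tm_C = tm_of_concentration(c_grid, models[[nm]]))))
}

#' Cellular setpoint arithmetic
#'
#' Converts a cellular abundance into a cytosolic concentration,
#' `c_nM = mass_fraction * total_protein * 1e6 / mw` (with total protein in
#' mg/ml and molecular weight in kDa), applies a nuclear enrichment factor to
#' obtain the local concentration, and, given a setpoint model, predicts the
#' transition midpoints at both concentrations. Alternatively the cytosolic
#' concentration can be supplied directly.
#'
#' @param enrichment_fold local (nuclear) enrichment factor (> 0)
#' @param mass_fraction protein mass fraction of total protein (used when
#'   `cytosolic_nM` is not given)
#' @param total_protein_mg_per_ml total cellular protein concentration
#' @param mw_kDa protein molecular weight
#' @param cytosolic_nM optionally, the cytosolic concentration directly (nM)
#' @param model optional [dimer_model()] for Tm predictions
#' @return list: `cytosolic_nM`, `local_nM`, and when a model is given
#'   `predicted_Tm_cytosolic_C`, `predicted_Tm_local_C`
#' @export
cellular_setpoint <- function(enrichment_fold, mass_fraction = NULL,
                              total_protein_mg_per_ml = 150, mw_kDa = 57.3,
                              cytosolic_nM = NULL, model = NULL) {
  assert_finite_scalar(enrichment_fold, "enrichment_fold", positive = TRUE)
  if (is.null(cytosolic_nM)) {
    assert_finite_scalar(mass_fraction, "mass_fraction", positive = TRUE)
    assert_finite_scalar(total_protein_mg_per_ml, "total_protein_mg_per_ml",
                         positive = TRUE)
    assert_finite_scalar(mw_kDa, "mw_kDa", positive = TRUE)
    cytosolic_nM <- mass_fraction * total_protein_mg_per_ml * 1e6 / mw_kDa
  } else {
    assert_finite_scalar(cytosolic_nM, "cytosolic_nM", positive = TRUE)
  }
  out <- list(cytosolic_nM = cytosolic_nM,
              local_nM = cytosolic_nM * enrichment_fold)
  if (!is.null(model)) {
    stopifnot(inherits(model, "dimer_model"))
    out$predicted_Tm_cytosolic_C <- tm_of_concentration(cytosolic_nM, model)
    out$predicted_Tm_local_C <- tm_of_concentration(out$local_nM, model)
  }
  out
}
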