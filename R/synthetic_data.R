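#' Fraction laws for synthetic exchange series
#'
#' A fraction law maps the condition axis (temperature or time) to the true
#' fraction of molecules in the high-exchanging state. `thermal_law` is the
#' two-state thermal transition used for temperature series (see
#' [thermal_model()]); `exponential_law` is a single-exponential relaxation
#' used for heat-shock time courses; `explicit_law` pins fractions point by
#' point.
#'
#' @param f0,fmax plateau fractions at low/high temperature
#' @param Tm_C transition midpoint in degrees Celsius
#' @param dH_J_mol apparent steepness parameter in J/mol (not a thermodynamic
#'   enthalpy; the transition is irreversible)
#' @param k_per_s rate constant in 1/s
#' @param f_start,f_end fractions at time 0 and at infinite time
#' @param fractions explicit per-condition fractions in \[0, 1\]
#' @return an object of class `fraction_law`
#' @export
thermal_law <- function(f0 = 0, fmax = 1, Tm_C = 36.15, dH_J_mol = 3.5e5) {
  assert_finite_scalar(f0, "f0"); assert_finite_scalar(fmax, "fmax")
  assert_finite_scalar(Tm_C, "Tm_C"); assert_finite_scalar(dH_J_mol, "dH_J_mol")
  structure(list(type = "thermal", f0 = f0, fmax = fmax, Tm_C = Tm_C,
                 dH_J_mol = dH_J_mol), class = "fraction_law")
}

#' @rdname thermal_law
#' @export
exponential_law <- function(k_per_s, f_start = 1, f_end = 0) {
  assert_finite_scalar(k_per_s, "k_per_s", positive = TRUE)
  assert_finite_scalar(f_start, "f_start"); assert_finite_scalar(f_end, "f_end")
  structure(list(type = "exponential", k_per_s = k_per_s, f_start = f_start,
                 f_end = f_end), class = "fraction_law")
}

#' @rdname thermal_law
#' @export
explicit_law <- function(fractions) {
  assert_finite_vector(fractions, "fractions")
  if (any(fractions < 0 | fractions > 1))
    stop("field 'fractions' must lie in [0, 1]", call. = FALSE)
  structure(list(type = "explicit", fractions = as.numeric(fractions)),
            class = "fraction_law")
}

# evaluate a (non-explicit) law at condition values
law_fraction <- function(law, x) {
  switch(law$type,
    thermal = {
      TK <- celsius_to_kelvin(x)
      thermal_model(TK, f0 = law$f0, fmax = law$fmax,
                    Tm_K = celsius_to_kelvin(law$Tm_C), dH = law$dH_J_mol)
    },
    exponential = law$f_end + (law$f_start - law$f_end) * exp(-law$k_per_s * x),
    stop("explicit laws are evaluated positionally, not by condition value",
         call. = FALSE))
}

#' Define a synthetic bimodal-exchange scenario
#'
#' Describes one peptide/charge envelope and how its high-exchanging fraction
#' evolves along a temperature or time axis. Defaults emulate a well-resolved
#' EX1 bimodal: two Gaussian subpopulation envelopes 2.8 m/z apart (5.6 sigma)
#' sampled on a 7-temperature grid spanning the transition, with 2 percent
#' additive intensity noise.
#'
#' @param peptide_id,charge peptide label and charge state
#' @param n_peaks number of isotope peaks (>= 6)
#' @param mz_start m/z of the first isotope peak (Da/e)
#' @param isotope_spacing isotopologue spacing in Da; applied per charge as
#'   `isotope_spacing / charge`. Default 1.00336 Da.
#' @param centroid_low,centroid_high centroids of the low- and high-exchanging
#'   subpopulation envelopes (Da/e; low < high)
#' @param sigma_true shared Gaussian width (Da/e)
#' @param condition_axis `"temperature_C"` or `"time_s"`
#' @param condition_values distinct condition values along the axis
#' @param fraction_law a [thermal_law()], [exponential_law()] or
#'   [explicit_law()] giving the true high-exchanging fraction per condition
#' @param noise_rel additive Gaussian intensity noise, as a fraction of the
#'   maximum noise-free peak intensity (truncated at zero)
#' @param total_area total envelope area in intensity x m/z units
#' @param seed integer seed; identical seed and scenario give bit-identical
#'   output
#' @return an object of class `exchange_scenario`
#' @export
exchange_scenario <- function(peptide_id = "378-395", charge = 2L,
                              n_peaks = 14L, mz_start = 1000,
                              isotope_spacing = 1.00336,
                              centroid_low = 1001.8, centroid_high = 1004.6,
                              sigma_true = 0.5,
                              condition_axis = c("temperature_C", "time_s"),
                              condition_values = seq(30, 42, by = 2),
                              fraction_law = thermal_law(),
                              noise_rel = 0.02, total_area = 1e5, seed = 1L) {
  condition_axis <- match.arg(condition_axis)
  n_peaks <- as.integer(n_peaks)
  if (is.na(n_peaks) || n_peaks < 6L)
    stop("field 'n_peaks' must be an integer >= 6", call. = FALSE)
  assert_finite_scalar(mz_start, "mz_start")
  assert_finite_scalar(isotope_spacing, "isotope_spacing", positive = TRUE)
  assert_finite_scalar(centroid_low, "centroid_low")
  assert_finite_scalar(centroid_high, "centroid_high")
  assert_finite_scalar(sigma_true, "sigma_true", positive = TRUE)
  assert_finite_scalar(noise_rel, "noise_rel", nonneg = TRUE)
  assert_finite_scalar(total_area, "total_area", positive = TRUE)
  assert_finite_vector(condition_values, "condition_values")
  if (anyDuplicated(condition_values))
    stop("field 'condition_values' must be distinct", call. = FALSE)
  if (centroid_low >= centroid_high)
    stop("field 'centroid_low' must be < centroid_high", call. = FALSE)
  if (!inherits(fraction_law, "fraction_law"))
    stop("field 'fraction_law' must be a fraction_law object", call. = FALSE)
  structure(
    list(peptide_id = peptide_id, charge = as.integer(charge),
         n_peaks = n_peaks, mz_start = mz_start,
         isotope_spacing = isotope_spacing, centroid_low = centroid_low,
         centroid_high = centroid_high, sigma_true = sigma_true,
         condition_axis = condition_axis,
         condition_values = as.numeric(condition_values),
         fraction_law = fraction_law, noise_rel = noise_rel,
         total_area = total_area, seed = as.integer(seed)),
    class = "exchange_scenario")
}

#' Simulate one bimodal isotope envelope
#'
#' Peaks sit on the grid `mz_start + i * isotope_spacing / charge`. The
#' noise-free intensity at each peak is the two-Gaussian mixture density at
#' the peak position, with component areas proportional to
#' `(1 - fraction_high)` and `fraction_high`, times the grid spacing, so peak
#' intensities sum to the total area (within discretization error). Additive
#' Gaussian noise (sd = `noise_rel` x max intensity) is truncated at zero.
#'
#' @param scenario an [exchange_scenario()]
#' @param fraction_high true fraction of the high-exchanging subpopulation,
#'   in \[0, 1\]
#' @param condition_value condition recorded on the cluster (defaults to the
#'   first of the scenario's condition values)
#' @param seed seed for the noise draw (defaults to the scenario seed)
#' @return an [isotope_cluster()]
#' @export
simulate_isotope_envelope <- function(scenario, fraction_high,
                                      condition_value = scenario$condition_values[1],
                                      seed = scenario$seed) {
  stopifnot(inherits(scenario, "exchange_scenario"))
  assert_finite_scalar(fraction_high, "fraction_high")
  if (fraction_high < 0 || fraction_high > 1)
    stop("fraction_high must lie in [0, 1]", call. = FALSE)
  dmz <- scenario$isotope_spacing / scenario$charge
  mz <- scenario$mz_start + (seq_len(scenario$n_peaks) - 1L) * dmz
  dens <- (1 - fraction_high) *
            stats::dnorm(mz, scenario$centroid_low, scenario$sigma_true) +
          fraction_high *
            stats::dnorm(mz, scenario$centroid_high, scenario$sigma_true)
  intensity <- scenario$total_area * dens * dmz
  if (scenario$noise_rel > 0) {
    sd_noise <- scenario$noise_rel * max(intensity)
    intensity <- withr::with_seed(seed, {
      pmax(0, intensity + stats::rnorm(length(intensity), sd = sd_noise))
    })
  }
  isotope_cluster(scenario$peptide_id, scenario$charge,
                  scenario$condition_axis, condition_value, mz, intensity)
}

#' Simulate a full exchange series
#'
#' One envelope per condition value; the true high-exchanging fraction at
#' each condition follows the scenario's fraction law. A thermal law requires
#' a temperature axis and an exponential law a time axis; an explicit law
#' must match the number of conditions. The true fractions are returned
#' alongside the clusters for recovery tests.
#'
#' @param scenario an [exchange_scenario()]
#' @return a list of class `exchange_series` with elements `clusters` (list of
#'   [isotope_cluster()]), `true_fractions` and `scenario`
#' @export
simulate_series <- function(scenario) {
  stopifnot(inherits(scenario, "exchange_scenario"))
  law <- scenario$fraction_law
  xs <- scenario$condition_values
  if (law$type == "thermal" && scenario$condition_axis != "temperature_C")
    stop("thermal fraction law requires a temperature_C condition axis",
         call. = FALSE)
  if (law$type == "exponential" && scenario$condition_axis != "time_s")
    stop("exponential fraction law requires a time_s condition axis",
         call. = FALSE)
  if (law$type == "explicit") {
    if (length(law$fractions) != length(xs))
      stop("explicit law length must match the number of condition values",
           call. = FALSE)
    fr <- law$fractions
  } else {
    fr <- law_fraction(law, xs)
  }
  stopifnot(all(fr >= 0 & fr <= 1))
  clusters <- lapply(seq_along(xs), function(i) {
    simulate_isotope_envelope(scenario, fr[i], condition_value = xs[i],
                              seed = scenario$seed + i)
  })
  structure(list(clusters = clusters, true_fractions = fr,
                 scenario = scenario), class = "exchange_series")
}

#' Define a synthetic anisotropy-titration scenario
#'
#' Emulates DNA-binding titrations of heat-shocked protein: for each
#' condition (a pre-incubation temperature/concentration giving some active
#' fraction of trimer), a serial dilution of the trimer is mixed with labelled
#' DNA and the anisotropy follows the quadratic binding equilibrium with the
#' active trimer concentration `active_fraction x trimer`.
#'
#' @param kd_nM trimer-DNA dissociation constant (nM)
#' @param r_min,r_max anisotropy of free and fully bound DNA (r_min < r_max)
#' @param dna_nM labelled DNA concentration (nM)
#' @param conditions data frame with columns `label`, `active_fraction`
#'   (in \[0, 1\]) and `top_trimer_nM` (highest theoretical trimer
#'   concentration in the dilution series)
#' @param dilution_factor serial dilution factor (> 1)
#' @param n_dilutions number of points per dilution series
#' @param noise_sd additive Gaussian noise on anisotropy
#' @param seed integer seed
#' @return an object of class `binding_scenario`
#' @export
binding_scenario <- function(kd_nM = 1.1, r_min = 0.08, r_max = 0.20,
                             dna_nM = 10,
                             conditions = data.frame(
                               label = c("100nM", "300nM", "1uM", "5uM"),
                               active_fraction = c(0, 0.2, 0.6, 0.9),
                               top_trimer_nM = c(100, 300, 1000, 5000) / 3),
                             dilution_factor = 2, n_dilutions = 12L,
                             noise_sd = 0.0024, seed = 1L) {
  assert_finite_scalar(kd_nM, "kd_nM", positive = TRUE)
  assert_finite_scalar(r_min, "r_min"); assert_finite_scalar(r_max, "r_max")
  if (r_min >= r_max) stop("field 'r_min' must be < r_max", call. = FALSE)
  assert_finite_scalar(dna_nM, "dna_nM", positive = TRUE)
  assert_finite_scalar(dilution_factor, "dilution_factor")
  if (dilution_factor <= 1)
    stop("field 'dilution_factor' must be > 1", call. = FALSE)
  assert_finite_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(is.data.frame(conditions),
            all(c("label", "active_fraction", "top_trimer_nM") %in%
                  names(conditions)))
  if (any(conditions$active_fraction < 0 | conditions$active_fraction > 1))
    stop("field 'active_fraction' must lie in [0, 1]", call. = FALSE)
  assert_finite_vector(conditions$top_trimer_nM, "top_trimer_nM",
                       positive = TRUE)
  structure(list(kd_nM = kd_nM, r_min = r_min, r_max = r_max, dna_nM = dna_nM,
                 conditions = conditions, dilution_factor = dilution_factor,
                 n_dilutions = as.integer(n_dilutions), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "binding_scenario")
}

#' Simulate anisotropy titrations
#'
#' @param scenario a [binding_scenario()]
#' @param replicate_id label recorded on every row
#' @return a list of class `anisotropy_dataset` with `data` (data frame:
#'   `condition`, `trimer_nM`, `anisotropy`, `replicate_id`) and the scenario
#'   as `truth`
#' @export
simulate_anisotropy <- function(scenario, replicate_id = "rep1") {
  stopifnot(inherits(scenario, "binding_scenario"))
  rows <- lapply(seq_len(nrow(scenario$conditions)), function(i) {
    cond <- scenario$conditions[i, ]
    trimer <- cond$top_trimer_nM /
      scenario$dilution_factor^(seq_len(scenario$n_dilutions) - 1L)
    stopifnot(all(diff(trimer) < 0))
    fb <- bound_fraction_quadratic(cond$active_fraction * trimer,
                                   scenario$dna_nM, scenario$kd_nM)
    data.frame(condition = cond$label, trimer_nM = trimer,
               anisotropy = scenario$r_min +
                 (scenario$r_max - scenario$r_min) * fb,
               replicate_id = replicate_id)
  })
  dat <- do.call(rbind, rows)
  if (scenario$noise_sd > 0) {
    dat$anisotropy <- withr::with_seed(scenario$seed, {
      dat$anisotropy + stats::rnorm(nrow(dat), sd = scenario$noise_sd)
    })
  }
  structure(list(data = dat, truth = scenario), class = "anisotropy_dataset")
}

#' Define and simulate a (concentration, Tm) dataset
#'
#' Emulates the scatter of transition midpoints measured at different total
#' protein concentrations, generated from a monomer-dimer setpoint model plus
#' Gaussian noise on Tm.
#'
#' @param model a [dimer_model()]
#' @param concentrations_nM total protein concentrations (monomer units, nM)
#' @param noise_sd_C Gaussian noise on Tm in degrees C
#' @param seed integer seed
#' @return an object of class `tm_scenario`
#' @export
tm_scenario <- function(model, concentrations_nM = c(50, 150, 500, 1500, 5000),
                        noise_sd_C = 0.3, seed = 1L) {
  stopifnot(inherits(model, "dimer_model"))
  assert_finite_vector(concentrations_nM, "concentrations_nM", positive = TRUE)
  assert_finite_scalar(noise_sd_C, "noise_sd_C", nonneg = TRUE)
  structure(list(model = model,
                 concentrations_nM = as.numeric(concentrations_nM),
                 noise_sd_C = noise_sd_C, seed = as.integer(seed)),
            class = "tm_scenario")
}

#' @rdname tm_scenario
#' @param scenario a `tm_scenario`
#' @return `simulate_tm_dataset`: data frame with `concentration_nM`, `Tm_C`
#' @export
simulate_tm_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "tm_scenario"))
  tm <- tm_of_concentration(scenario$concentrations_nM, scenario$model)
  if (scenario$noise_sd_C > 0) {
    tm <- withr::with_seed(scenario$seed, {
      tm + stats::rnorm(length(tm), sd = scenario$noise_sd_C)
    })
  }
  data.frame(concentration_nM = scenario$concentrations_nM, Tm_C = tm)
}
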