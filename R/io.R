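#' Read isotope-cluster spectra from CSV/TSV
#'
#' Expects a header `peptide_id, charge, condition_type, condition_value,
#' mz, intensity` (comma- or tab-separated, sniffed from the header line).
#' Rows are grouped into one [isotope_cluster()] per
#' (peptide_id, charge, condition_type, condition_value); all cluster
#' invariants (>= 4 peaks, strictly increasing m/z, near-uniform spacing,
#' non-negative intensity) are enforced, with offending rows identified by
#' line number.
#'
#' @param path path to the spectra file
#' @return list of [isotope_cluster()] objects
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  required <- c("peptide_id", "charge", "condition_type", "condition_value",
                "mz", "intensity")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, " (header line 1): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$.line <- seq_len(nrow(df)) + 1L
  neg <- which(df$intensity < 0)
  if (length(neg))
    stop("negative intensity at line ", df$.line[neg[1]], " of ", path,
         call. = FALSE)
  key <- paste(df$peptide_id, df$charge, df$condition_type,
               df$condition_value, sep = "\r")
  groups <- split(df, factor(key, levels = unique(key)))
  lapply(groups, function(g) {
    if (is.unsorted(g$mz, strictly = TRUE))
      stop("non-monotone m/z within cluster ", g$peptide_id[1], "/+",
           g$charge[1], " (", g$condition_type[1], " ", g$condition_value[1],
           ") near line ", g$.line[which(diff(g$mz) <= 0)[1] + 1L],
           call. = FALSE)
    cv <- if (g$condition_type[1] == "control") as.character(g$condition_value[1])
          else as.numeric(g$condition_value[1])
    isotope_cluster(as.character(g$peptide_id[1]), g$charge[1],
                    g$condition_type[1], cv, g$mz, g$intensity)
  })
}

#' Write isotope clusters to CSV
#'
#' Inverse of [read_spectra()]: one row per peak, full numeric precision
#' (values survive a write/read round trip to better than 1e-12).
#'
#' @param clusters a list of [isotope_cluster()] objects or an
#'   `exchange_series`
#' @param path output path
#' @return the path, invisibly
#' @export
write_spectra <- function(clusters, path) {
  if (inherits(clusters, "exchange_series")) clusters <- clusters$clusters
  if (inherits(clusters, "isotope_cluster")) clusters <- list(clusters)
  rows <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(peptide_id = cl$peptide_id, charge = cl$charge,
               condition_type = cl$condition_type,
               condition_value = as.character(cl$condition_value),
               mz = sprintf("%.15g", cl$peaks$mz),
               intensity = sprintf("%.15g", cl$peaks$intensity))))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a truth sidecar for a synthetic series
#'
#' Records the generating parameters and true per-condition fractions of an
#' `exchange_series` as JSON, so recovery tests and downstream reports can
#' compare fitted values against the generating truth.
#'
#' @param series an `exchange_series` from [simulate_series()]
#' @param path output path (JSON)
#' @return the path, invisibly
#' @export
write_truth <- function(series, path) {
  stopifnot(inherits(series, "exchange_series"))
  sc <- series$scenario
  jsonlite::write_json(
    list(scenario = sc[setdiff(names(sc), "fraction_law")],
         fraction_law = unclass(sc$fraction_law),
         condition_values = sc$condition_values,
         true_fractions = series$true_fractions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-spectrum fractions to TSV
#'
#' @param fractions the data frame from [series_fractions()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_fractions <- function(fractions, path) {
  utils::write.table(fractions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# conventions stated in every JSON report
report_conventions <- function(scale = "fraction") {
  list(fraction_scale = scale,
       temperature_interface_unit = "C",
       concentration_unit = "nM",
       dimer_fraction_convention = "units",
       dH_label = "apparent steepness parameter, not an unfolding enthalpy")
}

# replace non-finite leaves with NULL and set a flag, so no NaN/Inf reaches JSON
sanitize_report <- function(x) {
  flagged <- FALSE
  walk <- function(v) {
    if (is.list(v)) return(lapply(v, walk))
    if (is.numeric(v) && any(!is.finite(v))) {
      flagged <<- TRUE
      if (length(v) == 1L) return(NULL)
      v[!is.finite(v)] <- NA
    }
    v
  }
  out <- walk(x)
  out$has_nonfinite_fields <- flagged
  out
}

#' Write a JSON stage report
#'
#' Serializes a fit result with the run conventions echoed; non-finite
#' numeric fields are nulled and flagged rather than silently propagated.
#'
#' @param result a fit object (list-like)
#' @param path output path
#' @param config optional run configuration to echo verbatim
#' @param scale fraction scale convention in force
#' @return the report list, invisibly
#' @export
write_report <- function(result, path, config = NULL, scale = "fraction") {
  payload <- sanitize_report(
    list(result = unclass_deep(result),
         conventions = report_conventions(scale),
         config = config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(payload)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Run configuration for the pipeline
#'
#' @param seed integer seed applied to every stochastic stage
#' @param out_dir output directory for stage reports (created if needed)
#' @param scale fraction scale convention, `"fraction"` or `"percent"`
#' @param scenario an [exchange_scenario()] for the simulate stage; its seed
#'   is overridden by `seed`
#' @param spectra_path optional pre-existing spectra CSV consumed by the
#'   deconvolve stage when the simulate stage is not run
#' @param max_iter,tol,restarts optimizer settings forwarded to
#'   [fit_bimodal_series()]
#' @return a `run_config` list
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("hdxtherm_run_"),
                       scale = c("fraction", "percent"),
                       scenario = NULL, spectra_path = NULL,
                       max_iter = 500L, tol = 1e-10, restarts = 3L) {
  scale <- match.arg(scale)
  structure(list(seed = as.integer(seed), out_dir = out_dir, scale = scale,
                 scenario = scenario, spectra_path = spectra_path,
                 max_iter = max_iter, tol = tol, restarts = restarts),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Chains the core stages — `simulate` (synthetic exchange series),
#' `deconvolve` (global two-Gaussian fit and per-spectrum fractions),
#' `fit_transition` (thermal transition on the fractions) — in order,
#' writing one JSON report per stage into the configured output directory.
#' Output is deterministic given the configuration seed (reports carry no
#' timestamps). A required fit that does not converge aborts the run.
#'
#' @param config a [run_config()]
#' @param stages character vector, subset of
#'   `c("simulate", "deconvolve", "fit_transition")` in pipeline order; an
#'   empty vector is a valid no-op
#' @return a report bundle: named list with one entry per executed stage plus
#'   the echoed config
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "deconvolve",
                                    "fit_transition")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "deconvolve", "fit_transition")
  if (length(stages)) {
    stages <- match.arg(stages, all_stages, several.ok = TRUE)
    if (is.unsorted(match(stages, all_stages)))
      stop("stages must be given in pipeline order: ",
           paste(all_stages, collapse = " -> "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- list(seed = config$seed, scale = config$scale,
                   out_dir = config$out_dir, max_iter = config$max_iter,
                   tol = config$tol, restarts = config$restarts)
  bundle <- list(config = cfg_echo)
  series <- NULL
  fractions <- NULL

  if ("simulate" %in% stages) {
    scenario <- config$scenario
    if (is.null(scenario)) scenario <- exchange_scenario(seed = config$seed)
    else scenario$seed <- config$seed
    series <- simulate_series(scenario)
    write_spectra(series, file.path(config$out_dir, "spectra.csv"))
    write_truth(series, file.path(config$out_dir, "truth.json"))
    bundle$simulate <- write_report(
      list(n_spectra = length(series$clusters),
           condition_values = scenario$condition_values,
           true_fractions = series$true_fractions),
      file.path(config$out_dir, "report_simulate.json"),
      config = cfg_echo, scale = config$scale)
  }

  if ("deconvolve" %in% stages) {
    clusters <- if (!is.null(series)) series$clusters
      else if (!is.null(config$spectra_path)) read_spectra(config$spectra_path)
      else stop("deconvolve stage: missing upstream artifact ",
                "(no simulated series and no spectra_path)", call. = FALSE)
    fit <- fit_bimodal_series(clusters, restarts = config$restarts,
                              max_iter = config$max_iter, tol = config$tol)
    if (!fit$converged)
      stop("deconvolve stage: bimodal series fit did not converge",
           call. = FALSE)
    fractions <- series_fractions(fit)
    write_fractions(fractions, file.path(config$out_dir, "fractions.tsv"))
    bundle$deconvolve <- write_report(
      fit[c("peptide_id", "charge", "mu1_bar", "mu2_bar", "sigma",
            "se_mu1_bar", "se_mu2_bar", "se_sigma", "per_spectrum",
            "converged", "mu1_unidentifiable", "mu2_unidentifiable")],
      file.path(config$out_dir, "report_deconvolve.json"),
      config = cfg_echo, scale = config$scale)
  }

  if ("fit_transition" %in% stages) {
    if (is.null(fractions)) {
      fp <- file.path(config$out_dir, "fractions.tsv")
      if (!file.exists(fp))
        stop("fit_transition stage: missing upstream artifact ",
             "(fractions.tsv not found)", call. = FALSE)
      fractions <- utils::read.table(fp, header = TRUE, sep = "\t")
    }
    keep <- fractions$condition_type == "temperature_C"
    if (!any(keep))
      stop("fit_transition stage: no temperature-axis fractions available",
           call. = FALSE)
    tf <- fit_thermal_transition(fractions$condition_value[keep],
                                 fractions$f_high[keep],
                                 scale = config$scale)
    if (!tf$converged)
      stop("fit_transition stage: transition fit did not converge",
           call. = FALSE)
    bundle$fit_transition <- write_report(
      tf, file.path(config$out_dir, "report_transition.json"),
      config = cfg_echo, scale = config$scale)
  }
  bundle
}
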