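#' Construct an isotope cluster
#'
#' The raw unit of HDX evidence: one centroided isotope envelope (m/z,
#' intensity pairs) for one peptide at one charge state and one condition.
#' Conditions are either numeric (a pre-incubation temperature in degrees C or
#' a heat-shock time in seconds) or a control tag (`"unexchanged"`,
#' `"fully_deuterated"`).
#'
#' @param peptide_id character label, conventionally the residue range
#'   (e.g. `"378-395"`)
#' @param charge positive integer charge state
#' @param condition_type one of `"temperature_C"`, `"time_s"`, `"control"`
#' @param condition_value numeric condition, or one of the control tags when
#'   `condition_type = "control"`
#' @param mz,intensity numeric vectors of equal length: peak positions (Da/e,
#'   strictly increasing, at least 4 peaks, consecutive spacing within 20
#'   percent of the median spacing) and non-negative intensities
#' @return an object of class `isotope_cluster`
#' @export
isotope_cluster <- function(peptide_id, charge, condition_type,
                            condition_value, mz, intensity) {
  if (!is.character(peptide_id) || length(peptide_id) != 1L)
    stop("peptide_id must be a single character label", call. = FALSE)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop("charge must be a positive integer", call. = FALSE)
  condition_type <- match.arg(condition_type,
                              c("temperature_C", "time_s", "control"))
  if (condition_type == "control") {
    condition_value <- match.arg(condition_value,
                                 c("unexchanged", "fully_deuterated"))
  } else {
    assert_finite_scalar(condition_value, "condition_value")
  }
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(mz) < 4L)
    stop("cluster ", peptide_id, "/+", charge, " (", condition_type, " ",
         condition_value, "): fewer than 4 peaks", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity values", call. = FALSE)
  if (any(diff(mz) <= 0))
    stop("cluster ", peptide_id, "/+", charge,
         ": m/z values must be strictly increasing", call. = FALSE)
  if (any(intensity < 0))
    stop("cluster ", peptide_id, "/+", charge,
         ": negative intensity", call. = FALSE)
  sp <- diff(mz)
  med <- stats::median(sp)
  if (any(abs(sp - med) > 0.2 * med))
    stop("cluster ", peptide_id, "/+", charge,
         ": peak spacing deviates more than 20% from the median spacing",
         call. = FALSE)
  structure(
    list(peptide_id = peptide_id, charge = charge,
         condition_type = condition_type, condition_value = condition_value,
         peaks = data.frame(mz = as.numeric(mz),
                            intensity = as.numeric(intensity))),
    class = "isotope_cluster")
}

#' @export
print.isotope_cluster <- function(x, ...) {
  cat(sprintf("<isotope_cluster> %s +%d  %s = %s  (%d peaks, %.4f-%.4f m/z)\n",
              x$peptide_id, x$charge, x$condition_type,
              as.character(x$condition_value), nrow(x$peaks),
              min(x$peaks$mz), max(x$peaks$mz)))
  invisible(x)
}
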