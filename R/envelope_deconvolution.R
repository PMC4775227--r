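#' Two-Gaussian mixture intensity model
#'
#' The bimodal envelope model for EX1-type exchange: intensity at m/z value
#' `mu` is the sum of two Gaussian peaks sharing one width,
#' `A1/(sigma*sqrt(2*pi)) * exp(-((mu - mu1)/sigma)^2 / 2) +
#'  A2/(sigma*sqrt(2*pi)) * exp(-((mu - mu2)/sigma)^2 / 2)`,
#' where `A1`, `A2` are the areas of the low- and high-exchanging
#' subpopulation envelopes and `mu1`, `mu2` their centroids.
#'
#' @param mu m/z value(s) at which to evaluate (Da/e)
#' @param A1,A2 component areas (>= 0)
#' @param mu1,mu2 component centroids (Da/e)
#' @param sigma shared Gaussian width (Da/e, > 0)
#' @return intensity value(s)
#' @export
evaluate_bimodal <- function(mu, A1, A2, mu1, mu2, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  A1 * stats::dnorm(mu, mu1, sigma) + A2 * stats::dnorm(mu, mu2, sigma)
}

# stack all peaks of a series into one table with a spectrum index
stack_series <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(s) {
    p <- clusters[[s]]$peaks
    data.frame(spectrum = s, mz = p$mz, intensity = p$intensity)
  }))
}

#' Globally fit the two-Gaussian mixture to a series of isotope clusters
#'
#' All intensity values of one temperature or time series are fitted jointly
#' by nonlinear least squares, with the two centroids and the width shared
#' across the series and the two component areas free per spectrum. Fitting is
#' performed at the observed discrete peak positions only. Control spectra
#' (unexchanged / fully deuterated), if present, inform the initialization of
#' the centroids but are excluded from the fit itself.
#'
#' Initialization: the low centroid from the intensity-weighted centroid of
#' the lowest-condition spectrum (or the unexchanged control), the high
#' centroid from the highest-condition spectrum (or the fully deuterated
#' control), the width from the RMS width of the lowest-condition spectrum,
#' and areas from an 11-point fraction grid per spectrum. Up to `restarts`
#' jittered restarts are attempted before the fit is flagged non-convergent.
#'
#' If one component carries less than 2 percent of the total area in every
#' spectrum, its centroid is not determined by the data and is flagged
#' unidentifiable.
#'
#' @param series an `exchange_series` from [simulate_series()], or a list of
#'   [isotope_cluster()] objects sharing peptide and charge
#' @param restarts maximum number of jittered restarts
#' @param max_iter maximum Levenberg-Marquardt iterations per start
#' @param tol relative SSE convergence tolerance
#' @return an object of class `bimodal_series_fit`: shared `mu1_bar`,
#'   `mu2_bar`, `sigma` (with standard errors), a `per_spectrum` data frame
#'   (condition, areas `A1`/`A2`, `f_high`, `se_f_high`, `sse`), convergence
#'   and identifiability flags
#' @export
fit_bimodal_series <- function(series, restarts = 3L, max_iter = 500L,
                               tol = 1e-10) {
  clusters <- if (inherits(series, "exchange_series")) series$clusters
              else series
  if (!length(clusters)) stop("empty series", call. = FALSE)
  stopifnot(all(vapply(clusters, inherits, logical(1), "isotope_cluster")))
  pid <- unique(vapply(clusters, `[[`, character(1), "peptide_id"))
  chg <- unique(vapply(clusters, `[[`, integer(1), "charge"))
  if (length(pid) != 1L || length(chg) != 1L)
    stop("all clusters in a series must share peptide_id and charge",
         call. = FALSE)
  bad <- vapply(clusters, function(cl) nrow(cl$peaks) < 4L, logical(1))
  if (any(bad))
    stop("cluster(s) with fewer than 4 peaks rejected: ",
         paste(vapply(clusters[bad], function(cl)
           paste0(cl$peptide_id, "/+", cl$charge, " @",
                  cl$condition_value), character(1)), collapse = ", "),
         call. = FALSE)

  is_ctrl <- vapply(clusters, function(cl) cl$condition_type == "control",
                    logical(1))
  ctrls <- clusters[is_ctrl]
  fitted_clusters <- clusters[!is_ctrl]
  if (!length(fitted_clusters))
    stop("series contains only control spectra", call. = FALSE)
  cond <- vapply(fitted_clusters, function(cl) as.numeric(cl$condition_value),
                 numeric(1))
  ord <- order(cond)
  fitted_clusters <- fitted_clusters[ord]
  cond <- cond[ord]
  S <- length(fitted_clusters)
  tab <- stack_series(fitted_clusters)

  # ---- initialization -------------------------------------------------------
  ctrl_of <- function(tag) {
    hit <- Filter(function(cl) identical(cl$condition_value, tag), ctrls)
    if (length(hit)) hit[[1]] else NULL
  }
  lo_cl <- ctrl_of("unexchanged") %||% fitted_clusters[[1]]
  hi_cl <- ctrl_of("fully_deuterated") %||% fitted_clusters[[S]]
  mu1_0 <- weighted_centroid(lo_cl$peaks$mz, lo_cl$peaks$intensity)
  mu2_0 <- weighted_centroid(hi_cl$peaks$mz, hi_cl$peaks$intensity)
  w <- lo_cl$peaks$intensity / sum(lo_cl$peaks$intensity)
  sigma_0 <- sqrt(sum(w * (lo_cl$peaks$mz - mu1_0)^2))
  span <- max(tab$mz) - min(tab$mz)
  if (!is.finite(sigma_0) || sigma_0 <= 0) sigma_0 <- span / 6
  if (mu2_0 - mu1_0 < 1e-3) {
    # degenerate (unimodal) series: keep the observed centroid on the low
    # component so the unused high component ends up with zero area
    mu2_0 <- mu1_0 + span / 4
  }
  dmz <- stats::median(diff(fitted_clusters[[1]]$peaks$mz))
  area_init <- function(cl) {
    tot <- sum(cl$peaks$intensity) * dmz
    fr <- seq(0, 1, by = 0.1)
    sse <- vapply(fr, function(f) {
      pred <- evaluate_bimodal(cl$peaks$mz, (1 - f) * tot, f * tot,
                               mu1_0, mu2_0, sigma_0)
      sum((cl$peaks$intensity - pred)^2)
    }, numeric(1))
    f <- fr[which.min(sse)]
    c((1 - f) * tot, f * tot)
  }
  A0 <- vapply(fitted_clusters, area_init, numeric(2))

  # parameters: mu1, dmu (= mu2 - mu1 > 0), sigma, then A1/A2 per spectrum
  p0 <- c(mu1 = mu1_0, dmu = max(mu2_0 - mu1_0, 1e-3), sigma = sigma_0,
          as.numeric(A0))
  lower <- c(-Inf, 1e-6, 1e-6, rep(0, 2 * S))
  upper <- c(Inf, span, span, rep(Inf, 2 * S))
  resid_fun <- function(p) {
    a <- matrix(p[-(1:3)], nrow = 2)
    pred <- evaluate_bimodal(tab$mz, a[1, tab$spectrum], a[2, tab$spectrum],
                             p[1], p[1] + p[2], p[3])
    tab$intensity - pred
  }

  jitters <- list(c(1, 1, 1), c(1.0005, 0.85, 1.2), c(0.9995, 1.15, 0.8),
                  c(1.001, 0.7, 1.5))
  best <- NULL
  for (j in seq_len(min(restarts + 1L, length(jitters)))) {
    pj <- p0
    pj[1] <- p0[1] * jitters[[j]][1]
    pj[2] <- p0[2] * jitters[[j]][2]
    pj[3] <- min(max(p0[3] * jitters[[j]][3], 2e-6), span)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pj, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = tol, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:3
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best$converged <- conv
    }
    if (conv && j == 1L) break        # first start already converged
  }
  if (is.null(best))
    stop("bimodal series fit failed for all starts", call. = FALSE)

  p <- best$par
  mu1 <- p[[1]]; mu2 <- p[[1]] + p[[2]]; sigma <- p[[3]]
  A <- matrix(p[-(1:3)], nrow = 2)

  # covariance of all parameters from J'J, residual variance pooled
  np <- length(p)
  dof <- max(nrow(tab) - np, 1L)
  s2 <- best$deviance / dof
  covm <- tryCatch({
    h <- as.matrix(best$hessian)      # J'J from nls.lm
    s2 * solve(h)
  }, error = function(e) matrix(NA_real_, np, np))

  se_shared <- sqrt(pmax(diag(covm)[1:3], 0))
  se_mu2 <- sqrt(max(covm[1, 1] + covm[2, 2] + 2 * covm[1, 2], 0))

  per <- lapply(seq_len(S), function(s) {
    cl <- fitted_clusters[[s]]
    idx1 <- 3L + 2L * (s - 1L) + 1L
    idx2 <- idx1 + 1L
    a1 <- A[1, s]; a2 <- A[2, s]
    pred <- evaluate_bimodal(cl$peaks$mz, a1, a2, mu1, mu2, sigma)
    sse <- sum((cl$peaks$intensity - pred)^2)
    tot <- a1 + a2
    fh <- if (tot > 0) a2 / tot else NA_real_
    # delta method on (A1, A2) for f = A2/(A1+A2)
    se_fh <- NA_real_
    if (tot > 0 && all(is.finite(covm[c(idx1, idx2), c(idx1, idx2)]))) {
      g <- c(-a2, a1) / tot^2
      v <- drop(t(g) %*% covm[c(idx1, idx2), c(idx1, idx2)] %*% g)
      se_fh <- sqrt(max(v, 0))
    }
    data.frame(condition_type = cl$condition_type,
               condition_value = as.numeric(cl$condition_value),
               A1 = a1, A2 = a2, f_high = fh, se_f_high = se_fh, sse = sse)
  })
  per <- do.call(rbind, per)

  share2 <- max(per$A2 / pmax(per$A1 + per$A2, 1e-300))
  share1 <- max(per$A1 / pmax(per$A1 + per$A2, 1e-300))
  structure(
    list(peptide_id = pid, charge = chg,
         mu1_bar = mu1, mu2_bar = mu2, sigma = sigma,
         se_mu1_bar = se_shared[[1]], se_mu2_bar = se_mu2,
         se_sigma = se_shared[[3]],
         per_spectrum = per, clusters = fitted_clusters,
         converged = isTRUE(best$converged),
         mu1_unidentifiable = share1 < 0.02,
         mu2_unidentifiable = share2 < 0.02,
         deviance = best$deviance, niter = best$niter,
         covariance = covm),
    class = "bimodal_series_fit")
}

#' @export
print.bimodal_series_fit <- function(x, ...) {
  cat(sprintf("<bimodal_series_fit> %s +%d: mu1=%.4f mu2=%.4f sigma=%.4f (%s)\n",
              x$peptide_id, x$charge, x$mu1_bar, x$mu2_bar, x$sigma,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (x$mu1_unidentifiable) cat("  note: low-exchanging centroid unidentifiable (A1 < 2% everywhere)\n")
  if (x$mu2_unidentifiable) cat("  note: high-exchanging centroid unidentifiable (A2 < 2% everywhere)\n")
  print(x$per_spectrum[, c("condition_value", "A1", "A2", "f_high")],
        row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attribute per-peak intensity to the two subpopulations
#'
#' Each observed peak intensity is split between the low- and high-exchanging
#' subpopulations in proportion to the two fitted component densities at that
#' peak's m/z, so that the split conserves the observed intensity exactly.
#' The high-exchanging fraction is the ratio of summed high-component
#' intensity to total intensity. Peaks beyond both tails (both densities
#' vanish) are split 50/50 with a warning; they carry negligible intensity.
#'
#' @param cluster an [isotope_cluster()] belonging to the fitted series
#' @param fit a converged [fit_bimodal_series()] result
#' @return an object of class `subpopulation_split`: per-peak data frame
#'   (`mz`, `intensity`, `intensity_low`, `intensity_high`) plus `f_high` and
#'   `f_low`
#' @export
split_peak_intensities <- function(cluster, fit) {
  stopifnot(inherits(cluster, "isotope_cluster"),
            inherits(fit, "bimodal_series_fit"))
  if (!fit$converged)
    stop("refusing to split intensities with a non-converged fit",
         call. = FALSE)
  row <- which(fit$per_spectrum$condition_type == cluster$condition_type &
               fit$per_spectrum$condition_value ==
                 as.numeric(cluster$condition_value))
  if (length(row) != 1L)
    stop("cluster condition not found in the fitted series", call. = FALSE)
  a1 <- fit$per_spectrum$A1[row]
  a2 <- fit$per_spectrum$A2[row]
  mz <- cluster$peaks$mz
  g1 <- a1 * stats::dnorm(mz, fit$mu1_bar, fit$sigma)
  g2 <- a2 * stats::dnorm(mz, fit$mu2_bar, fit$sigma)
  tot <- g1 + g2
  w_high <- ifelse(tot > 0, g2 / pmax(tot, .Machine$double.xmin), 0.5)
  degenerate <- tot <= 0 |
    tot < 1e-14 * max(tot)
  if (any(degenerate)) {
    w_high[degenerate] <- 0.5
    warning(sum(degenerate),
            " peak(s) beyond both component tails split 50/50", call. = FALSE)
  }
  I <- cluster$peaks$intensity
  ihigh <- I * w_high
  ilow <- I - ihigh                          # conservation exact by construction
  fh <- if (sum(I) > 0) sum(ihigh) / sum(I) else NA_real_
  structure(list(peaks = data.frame(mz = mz, intensity = I,
                                    intensity_low = ilow,
                                    intensity_high = ihigh),
                 f_high = fh, f_low = 1 - fh),
            class = "subpopulation_split")
}

#' High-exchanging fractions for a whole fitted series
#'
#' Convenience wrapper applying [split_peak_intensities()] to every spectrum
#' of a fit; this is the per-spectrum fraction the transition and kinetics
#' fits consume.
#'
#' @param fit a converged [fit_bimodal_series()] result
#' @return data frame: `peptide_id`, `charge`, `condition_type`,
#'   `condition_value`, `f_high`, `se_f_high`, `converged`
#' @export
series_fractions <- function(fit) {
  stopifnot(inherits(fit, "bimodal_series_fit"))
  fh <- vapply(fit$clusters, function(cl)
    split_peak_intensities(cl, fit)$f_high, numeric(1))
  data.frame(peptide_id = fit$peptide_id, charge = fit$charge,
             condition_type = fit$per_spectrum$condition_type,
             condition_value = fit$per_spectrum$condition_value,
             f_high = fh, se_f_high = fit$per_spectrum$se_f_high,
             converged = fit$converged)
}

#' Centroid deuterium uptake with back-exchange correction
#'
#' Computes the intensity-weighted centroid of an envelope and converts the
#' centroid shift relative to the unexchanged control into deuterons
#' (charge-corrected). The corrected uptake rescales the shift by the fully
#' deuterated control (two-point correction), so the unexchanged control maps
#' to 0 and the fully deuterated control to the number of exchangeable
#' amides.
#'
#' @param cluster the exchanged envelope
#' @param unexchanged,fully_deuterated control envelopes (same peptide and
#'   charge)
#' @param n_exchangeable number of exchangeable backbone amides for the
#'   peptide
#' @return an object of class `uptake_result`: `centroid` (Da/e),
#'   `deuterons` (raw, Da) and `corrected_deuterons`
#' @export
centroid_uptake <- function(cluster, unexchanged, fully_deuterated,
                            n_exchangeable) {
  for (cl in list(cluster, unexchanged, fully_deuterated))
    stopifnot(inherits(cl, "isotope_cluster"))
  same <- function(a, b) a$peptide_id == b$peptide_id && a$charge == b$charge
  if (!same(cluster, unexchanged) || !same(cluster, fully_deuterated))
    stop("all three clusters must share peptide and charge", call. = FALSE)
  assert_finite_scalar(n_exchangeable, "n_exchangeable", positive = TRUE)
  c_obs <- weighted_centroid(cluster$peaks$mz, cluster$peaks$intensity)
  c_0 <- weighted_centroid(unexchanged$peaks$mz, unexchanged$peaks$intensity)
  c_100 <- weighted_centroid(fully_deuterated$peaks$mz,
                             fully_deuterated$peaks$intensity)
  if (c_100 <= c_0)
    stop("fully deuterated centroid must exceed the unexchanged centroid",
         call. = FALSE)
  structure(list(centroid = c_obs,
                 deuterons = (c_obs - c_0) * cluster$charge,
                 corrected_deuterons =
                   n_exchangeable * (c_obs - c_0) / (c_100 - c_0)),
            class = "uptake_result")
}

#' Per-peptide uptake differences against a reference condition
#'
#' Computes, for every peptide, the difference in (corrected) deuteron uptake
#' between each condition and a reference condition (e.g. pre-incubation at
#' 20 degrees C), with replicate SEMs propagated in quadrature. Replicate
#' rows, if present, are first aggregated to mean and SEM per peptide and
#' condition.
#'
#' @param uptake data frame with columns `peptide_id`, `condition_value`,
#'   `uptake` and optionally `replicate_id` (or an `sem` column if already
#'   aggregated)
#' @param reference_condition the condition value used as baseline; must be
#'   present for every peptide
#' @return data frame: `peptide_id`, `condition_value`, `delta_uptake`,
#'   `sem_delta`
#' @export
uptake_difference <- function(uptake, reference_condition) {
  stopifnot(is.data.frame(uptake),
            all(c("peptide_id", "condition_value", "uptake") %in%
                  names(uptake)))
  if (!"sem" %in% names(uptake)) {
    agg_m <- stats::aggregate(uptake ~ peptide_id + condition_value,
                              data = uptake, FUN = mean)
    agg_s <- stats::aggregate(uptake ~ peptide_id + condition_value,
                              data = uptake,
                              FUN = function(v)
                                if (length(v) > 1)
                                  stats::sd(v) / sqrt(length(v)) else 0)
    names(agg_s)[3] <- "sem"
    uptake <- merge(agg_m, agg_s)
  }
  out <- lapply(split(uptake, uptake$peptide_id), function(d) {
    ref <- d[d$condition_value == reference_condition, ]
    if (nrow(ref) != 1L)
      stop("reference condition ", reference_condition,
           " missing for peptide ", d$peptide_id[1], call. = FALSE)
    data.frame(peptide_id = d$peptide_id,
               condition_value = d$condition_value,
               delta_uptake = d$uptake - ref$uptake,
               sem_delta = sqrt(d$sem^2 + ref$sem^2))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
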