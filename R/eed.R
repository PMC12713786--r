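#' Collapse a multi-site study to percentile entries
#'
#' A single survey quantifying many treatment plants would dominate the
#' exposure data set. Per-plant averaging is applied first (one entry per
#' site as the mean of its samples); if a study still exceeds `max_entries`
#' sites, its values are replaced by the bootstrap-median estimates of the
#' 10th..90th percentiles (steps of 10) of a log-normal fit — nine strictly
#' increasing values representing the study's spread.
#'
#' @param samples exposure samples of ONE study (data.frame as from
#'   [load_exposure_table()]).
#' @param max_entries site cap above which the collapse triggers (default 9).
#' @param n_boot bootstrap iterations for the percentile estimates.
#' @param seed RNG seed.
#' @return reduced data.frame in the same shape; collapsed rows get
#'   `sample_id` `<study>_p10` .. `<study>_p90`.
#' @export
collapse_multisite_study <- function(samples, max_entries = 9L,
                                     n_boot = 1001L, seed = 1L) {
  samples <- as.data.frame(samples)
  stopifnot(nrow(samples) >= 1L)
  # normalize to the canonical columns so collapsed and pass-through
  # branches rbind cleanly
  if (!"matrix" %in% names(samples)) samples$matrix <- NA_character_
  samples <- samples[c("sample_id", "study_id", "site_id", "matrix",
                       "concentration")]
  study <- samples$study_id[1L]
  # per-site averaging first
  by_site <- split(samples$concentration,
                   factor(samples$site_id, levels = unique(samples$site_id)))
  site_mean <- vapply(by_site, mean, numeric(1))
  first_idx <- vapply(names(by_site),
                      function(s) which(samples$site_id == s)[1L], integer(1))
  out <- samples[first_idx, , drop = FALSE]
  out$concentration <- unname(site_mean)
  rownames(out) <- NULL
  if (nrow(out) <= max_entries) return(out)
  ps <- seq(0.1, 0.9, by = 0.1)
  est <- tryCatch({
    fit <- fit_mle(out$concentration, "lognormal")
    bt <- parametric_bootstrap(fit, n_boot = n_boot, ps = ps, seed = seed)
    bt$percentiles$boot_median
  }, error = function(e) {
    warning(sprintf("multisite collapse of study '%s' failed (%s); passing sites through",
                    study, conditionMessage(e)), call. = FALSE)
    NULL
  })
  if (is.null(est)) return(out)
  data.frame(sample_id = sprintf("%s_p%d", study, as.integer(ps * 100)),
             study_id = study, site_id = sprintf("p%d", as.integer(ps * 100)),
             matrix = out$matrix[1L], concentration = est,
             stringsAsFactors = FALSE)
}

#' Build an environmental exposure distribution
#'
#' Fits the EED candidate families (default all five: log-normal,
#' log-logistic, Burr XII, Weibull, gamma) to the per-entry concentrations
#' of one matrix, selects by lowest AIC, bootstraps, and reports the
#' 5th/50th/95th percentiles plus the raw empirical median (midpoint
#' convention for even n, i.e. `stats::median`).
#'
#' @param samples exposure samples (data.frame or positive numeric vector).
#' @param matrix label: `"sludge"`, `"sas"`, `"control"` or
#'   `"diluted_sludge"`.
#' @param config run configuration ([risk_config()]); uses `eed_families`,
#'   `n_boot`, `seed`.
#' @return object of class `mp_eed`: `matrix`, `fit`, `ranking`, `ensemble`,
#'   `percentiles`, `empirical_median`, `n_samples`, `dilution` (1 for raw
#'   fits).
#' @export
build_eed <- function(samples, matrix, config = risk_config()) {
  values <- if (is.data.frame(samples)) samples$concentration else samples
  if (length(values) < 10L) {
    stop_mp("EED for '%s': need >= 10 samples, got %d", matrix, length(values),
            class = "mp_precondition_error")
  }
  sel <- select_by_aic(values, config$eed_families)
  bt <- parametric_bootstrap(sel$fit, n_boot = config$n_boot,
                             ps = c(0.05, 0.5, 0.95),
                             seed = derive_seed(config$seed,
                                                paste0("eed_", matrix)))
  structure(list(matrix = matrix, fit = sel$fit, ranking = sel$ranking,
                 ensemble = bt$ensemble, percentiles = bt$percentiles,
                 empirical_median = stats::median(values),
                 n_samples = length(values), dilution = 1),
            class = "mp_eed")
}

#' @export
print.mp_eed <- function(x, ...) {
  cat(sprintf("<mp_eed> %s: %s fit to %d samples (dilution %g)\n",
              x$matrix, x$fit$family, x$n_samples, x$dilution))
  print(x$percentiles, row.names = FALSE)
  invisible(x)
}

#' Sludge-to-soil dilution factor
#'
#' The realistic exposure scenario divides the sludge concentrations by the
#' ratio of the sludge and sludge-amended-soil median concentrations
#' (bootstrap-median estimates of the 50th percentiles). The rounded integer
#' is the scenario factor.
#'
#' @param eed_sludge,eed_sas fitted EEDs ([build_eed()]).
#' @return list with `ratio` (raw) and `factor` (rounded to integer).
#' @export
dilution_factor <- function(eed_sludge, eed_sas) {
  m_sludge <- eed_sludge$percentiles$boot_median[eed_sludge$percentiles$p == 0.5]
  m_sas <- eed_sas$percentiles$boot_median[eed_sas$percentiles$p == 0.5]
  if (m_sas <= 0) stop_mp("SAS median is zero; dilution undefined",
                          class = "mp_precondition_error")
  ratio <- m_sludge / m_sas
  if (ratio < 1) {
    warning("sludge median below SAS median: dilution factor < 1 (reported unclamped)",
            call. = FALSE)
  }
  list(ratio = ratio, factor = round(ratio))
}

#' Dilute an exposure distribution
#'
#' All five families are scale families in the pinned parameterizations, so
#' dilution by a factor d is exact in the parameter domain: the scale
#' parameter (meanlog for the log-normal: `meanlog - log(d)`) is divided by
#' d in the point fit and in every bootstrap draw, making every percentile
#' of the output equal to the input percentile / d.
#'
#' @param eed an `mp_eed`.
#' @param factor dilution factor > 0 (>= 1 for physical scenarios).
#' @return a new `mp_eed` labelled `"diluted_<matrix>"` (unchanged when
#'   `factor == 1`).
#' @export
apply_dilution <- function(eed, factor) {
  stopifnot(inherits(eed, "mp_eed"))
  if (!is.finite(factor) || factor <= 0) {
    stop_mp("dilution factor must be > 0", class = "mp_precondition_error")
  }
  if (factor == 1) return(eed)
  out <- eed
  out$fit <- scale_fit(eed$fit, factor)
  out$ensemble <- scale_ensemble(eed$ensemble, factor)
  out$percentiles[c("point", "boot_median", "ci_low", "ci_high")] <-
    eed$percentiles[c("point", "boot_median", "ci_low", "ci_high")] / factor
  out$empirical_median <- eed$empirical_median / factor
  out$matrix <- paste0("diluted_", eed$matrix)
  out$dilution <- eed$dilution * factor
  out
}

# scale-parameter index per family (lognormal handled additively on meanlog)
scale_par_index <- function(family) {
  switch(family, lognormal = NA_integer_, loglogistic = 2L, burr = 3L,
         weibull = 2L, gamma = 2L)
}

scale_fit <- function(fit, factor) {
  p <- fit$params
  if (fit$family == "lognormal") p[["meanlog"]] <- p[["meanlog"]] - log(factor)
  else {
    i <- scale_par_index(fit$family)
    p[[i]] <- p[[i]] / factor
  }
  out <- fit
  out$params <- p
  out$data <- fit$data / factor
  # loglik/aic refer to the undiluted data; recompute on the scaled data
  out$loglik <- sum(family_spec(fit$family)$dfun(out$data, p, log = TRUE))
  out$aic <- 2 * length(p) - 2 * out$loglik
  out
}

scale_ensemble <- function(ensemble, factor) {
  pd <- ensemble$param_draws
  if (ensemble$family == "lognormal") pd[, "meanlog"] <- pd[, "meanlog"] - log(factor)
  else {
    i <- scale_par_index(ensemble$family)
    pd[, i] <- pd[, i] / factor
  }
  out <- ensemble
  out$param_draws <- pd
  out
}

#' Compliance fraction at a safety threshold
#'
#' The EED CDF evaluated at a threshold: the modelled fraction of samples
#' at or below it. Also reports the empirical fraction of the raw samples
#' at or below the threshold.
#'
#' @param eed an `mp_eed`.
#' @param threshold positive concentration (nb/kg dw).
#' @return list with `modelled` and `empirical` fractions.
#' @export
compliance_fraction <- function(eed, threshold) {
  stopifnot(inherits(eed, "mp_eed"))
  if (any(threshold <= 0)) {
    stop_mp("threshold must be > 0", class = "mp_precondition_error")
  }
  list(modelled = cdf_value(eed$fit, threshold),
       empirical = mean(eed$fit$data <= threshold))
}
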