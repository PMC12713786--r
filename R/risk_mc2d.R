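#' Two-dimensional Monte Carlo proportion of affected species
#'
#' Nested simulation separating uncertainty (which SSD/EED parameter set is
#' true) from variability (which species and which exposure a site
#' realizes). For each uncertainty iteration u one SSD parameter draw and
#' one EED parameter draw are taken (independently) from the bootstrap
#' ensembles; then `n_var` species thresholds are sampled from the SSD and
#' `n_var` independent exposure concentrations from the EED divided by the
#' dilution factor. A species is affected when its exposure exceeds its
#' threshold (strict inequality; ties have probability zero). The mean of
#' the affected indicator over the variability dimension gives one
#' proportion per uncertainty iteration; the result summarizes those
#' `n_unc` proportions by their median (point estimate; the mean is also
#' reported) and empirical 2.5th/97.5th percentiles (uncertainty interval).
#'
#' @param ssd_ens SSD bootstrap ensemble (`mp_ensemble`, or an `mp_ssd`).
#' @param eed_ens EED bootstrap ensemble (`mp_ensemble`, or an `mp_eed`).
#' @param factor dilution factor applied to the exposure side (>= 1).
#' @param n_var,n_unc variability / uncertainty iteration counts
#'   (default 1001 each).
#' @param seed integer seed; results are deterministic given the seed.
#' @param scenario label stored in the result.
#' @param shared_variability if TRUE, one matrix of uniform variates is
#'   shared across uncertainty iterations (classic two-dimensional Monte
#'   Carlo layout); default FALSE draws fresh variates per iteration.
#' @return object of class `mp_risk`: scenario, factor, `proportion_point`
#'   (median over uncertainty), `proportion_mean`, `unc_low`, `unc_high`,
#'   `n_var`, `n_unc`, `seed`, and the raw per-iteration `proportions`.
#' @export
simulate_proportion_affected <- function(ssd_ens, eed_ens, factor = 1,
                                         n_var = 1001L, n_unc = 1001L,
                                         seed = 1L, scenario = NULL,
                                         shared_variability = FALSE) {
  ssd_ens <- as_ensemble(ssd_ens)
  eed_ens <- as_ensemble(eed_ens)
  if (!is.finite(factor) || factor < 1) {
    stop_mp("dilution factor must be >= 1", class = "mp_precondition_error")
  }
  stopifnot(n_var >= 1L, n_unc >= 1L)
  qs <- family_spec(ssd_ens$family)$qfun
  qc <- family_spec(eed_ens$family)$qfun
  set.seed(as.integer(seed))
  iu_s <- sample.int(ssd_ens$B, n_unc, replace = TRUE)
  iu_c <- sample.int(eed_ens$B, n_unc, replace = TRUE)
  if (shared_variability) {
    u_s <- stats::runif(n_var)
    u_c <- stats::runif(n_var)
    us <- rep(u_s, times = n_unc)
    uc <- rep(u_c, times = n_unc)
  } else {
    us <- stats::runif(n_var * n_unc)
    uc <- stats::runif(n_var * n_unc)
  }
  idx <- rep(seq_len(n_unc), each = n_var)
  s_par <- lapply(seq_len(ncol(ssd_ens$param_draws)),
                  function(j) ssd_ens$param_draws[iu_s[idx], j])
  c_par <- lapply(seq_len(ncol(eed_ens$param_draws)),
                  function(j) eed_ens$param_draws[iu_c[idx], j])
  thresholds <- qs(us, s_par)
  exposures <- qc(uc, c_par) / factor
  affected <- exposures > thresholds
  proportions <- colMeans(matrix(affected, nrow = n_var, ncol = n_unc))
  structure(list(
    scenario = scenario %||% sprintf("dilution_%g", factor),
    factor = factor,
    proportion_point = stats::median(proportions),
    proportion_mean = mean(proportions),
    unc_low = unname(stats::quantile(proportions, 0.025)),
    unc_high = unname(stats::quantile(proportions, 0.975)),
    n_var = as.integer(n_var), n_unc = as.integer(n_unc),
    seed = as.integer(seed), proportions = proportions
  ), class = "mp_risk")
}

as_ensemble <- function(x) {
  if (inherits(x, "mp_ensemble")) return(x)
  if (inherits(x, c("mp_ssd", "mp_eed"))) return(x$ensemble)
  stop_mp("expected an mp_ensemble, mp_ssd or mp_eed", class = "mp_type_error")
}

#' @export
print.mp_risk <- function(x, ...) {
  cat(sprintf("<mp_risk> %s: %.1f%% affected [%.1f%%; %.1f%%] (n_var=%d, n_unc=%d)\n",
              x$scenario, 100 * x$proportion_point, 100 * x$unc_low,
              100 * x$unc_high, x$n_var, x$n_unc))
  invisible(x)
}

#' Risk sweep over dilution scenarios and matrices
#'
#' Runs [simulate_proportion_affected()] for the sludge EED at each dilution
#' factor, plus (undiluted) runs for any additional matrices supplied, e.g.
#' sludge-amended and control soils.
#'
#' @param ssd_ens SSD ensemble (or `mp_ssd`).
#' @param eed_ens_by_matrix named list of EED ensembles (or `mp_eed`s); the
#'   element named `"sludge"` is swept over `factors`, all others run at
#'   factor 1.
#' @param factors sorted dilution factors (>= 1), e.g. `c(1, 17)`.
#' @param config run configuration; uses `n_var`, `n_unc`, `seed`.
#' @return list of `mp_risk` results; see [risk_table()].
#' @export
scenario_sweep <- function(ssd_ens, eed_ens_by_matrix, factors = c(1, 17),
                           config = risk_config()) {
  stopifnot(all(factors >= 1), !is.unsorted(factors))
  results <- list()
  if ("sludge" %in% names(eed_ens_by_matrix)) {
    for (f in factors) {
      lab <- if (f == 1) "worst_case_sludge" else sprintf("sludge_dilution_%g", f)
      results[[lab]] <- simulate_proportion_affected(
        ssd_ens, eed_ens_by_matrix[["sludge"]], factor = f,
        n_var = config$n_var, n_unc = config$n_unc,
        seed = derive_seed(config$seed, paste0("mc2d_sludge_", f)),
        scenario = lab)
    }
  }
  for (m in setdiff(names(eed_ens_by_matrix), "sludge")) {
    results[[m]] <- simulate_proportion_affected(
      ssd_ens, eed_ens_by_matrix[[m]], factor = 1,
      n_var = config$n_var, n_unc = config$n_unc,
      seed = derive_seed(config$seed, paste0("mc2d_", m)), scenario = m)
  }
  results
}

#' Exceedance verdict against a protection threshold
#'
#' Compares each scenario's uncertainty interval with the acceptable
#' proportion of affected species (default 5%): `"exceeds"` when even the
#' lower uncertainty bound is above the threshold, `"below"` when the upper
#' bound is under it, `"intersects"` otherwise.
#'
#' @param results list of `mp_risk` results (or a single one).
#' @param threshold acceptable proportion, default 0.05.
#' @return data.frame: scenario, factor, proportion_point, unc_low,
#'   unc_high, verdict.
#' @export
exceedance_verdict <- function(results, threshold = 0.05) {
  if (inherits(results, "mp_risk")) results <- list(results)
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    verdict <- if (r$unc_low > threshold) "exceeds"
      else if (r$unc_high < threshold) "below" else "intersects"
    data.frame(scenario = r$scenario, factor = r$factor,
               proportion_point = r$proportion_point,
               unc_low = r$unc_low, unc_high = r$unc_high,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate risk results
#'
#' @param results list of `mp_risk` results.
#' @param threshold verdict threshold passed to [exceedance_verdict()].
#' @return data.frame with one row per scenario (proportions as fractions).
#' @export
risk_table <- function(results, threshold = 0.05) {
  v <- exceedance_verdict(results, threshold)
  extra <- data.frame(
    proportion_mean = vapply(results, function(r) r$proportion_mean, numeric(1)),
    n_var = vapply(results, function(r) r$n_var, integer(1)),
    n_unc = vapply(results, function(r) r$n_unc, integer(1)),
    seed = vapply(results, function(r) r$seed, integer(1)))
  cbind(v, extra)
}
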