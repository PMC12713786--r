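#' Build the species sensitivity distribution
#'
#' Fits the SSD candidate families (default log-normal, log-logistic, Burr
#' XII) to the per-species geometric-mean NOEC equivalents, selects by
#' lowest AIC, runs a parametric bootstrap and extracts the 5th (HC5), 50th
#' and 95th percentiles with two-sided 95% bootstrap intervals. The 5th
#' percentile of the SSD is the hazard concentration for 5% of species
#' (HC5); its upper 97.5% bootstrap bound (`hc5_upper`) is the optimistic
#' safety threshold used throughout reporting.
#'
#' @param sens species sensitivities ([aggregate_species()]) or a positive
#'   numeric vector of species values.
#' @param config run configuration ([risk_config()]); uses `ssd_families`,
#'   `n_boot`, `seed`, `min_species`.
#' @return object of class `mp_ssd`: list with `fit`, `ranking`, `ensemble`,
#'   `percentiles`, `hc5` (one-row data.frame), `hc5_upper`, `n_species`.
#' @export
build_ssd <- function(sens, config = risk_config()) {
  values <- if (is.data.frame(sens)) sens$geomean_noec_equivalent else sens
  floor_n <- config$min_species %||% 8L
  if (length(values) < floor_n) {
    stop_mp("only %d species value(s); an SSD needs at least %d — refusing to fit",
            length(values), floor_n, class = "mp_precondition_error")
  }
  sel <- select_by_aic(values, config$ssd_families)
  bt <- parametric_bootstrap(sel$fit, n_boot = config$n_boot,
                             ps = c(0.05, 0.5, 0.95),
                             seed = derive_seed(config$seed, "ssd_boot"))
  hc5 <- bt$percentiles[bt$percentiles$p == 0.05, , drop = FALSE]
  structure(list(fit = sel$fit, ranking = sel$ranking, ensemble = bt$ensemble,
                 percentiles = bt$percentiles, hc5 = hc5,
                 hc5_upper = hc5$ci_high, n_species = length(values)),
            class = "mp_ssd")
}

#' @export
print.mp_ssd <- function(x, ...) {
  cat(sprintf("<mp_ssd> %s fit to %d species\n", x$fit$family, x$n_species))
  cat(sprintf("HC5 (bootstrap median) = %.4g [%.4g; %.4g] nb/kg dw\n",
              x$hc5$boot_median, x$hc5$ci_low, x$hc5$ci_high))
  invisible(x)
}

#' Fraction of species affected at a concentration
#'
#' Reads the SSD CDF at a concentration: the fraction of species whose
#' chronic effect threshold lies below it.
#'
#' @param ssd an `mp_ssd`.
#' @param concentration positive concentration (nb/kg dw); vectorized.
#' @return probability in \[0, 1\].
#' @export
hazard_fraction <- function(ssd, concentration) {
  stopifnot(inherits(ssd, "mp_ssd"))
  if (any(concentration <= 0)) {
    stop_mp("concentration must be > 0", class = "mp_precondition_error")
  }
  cdf_value(ssd$fit, concentration)
}
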