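#' Run configuration
#'
#' Bundles every tunable of the pipeline with the conventional defaults:
#' 1001 bootstrap iterations and a 1001 x 1001 two-dimensional Monte Carlo
#' grid, dilution factors 1 (worst case) and 17 (realistic), three SSD
#' candidate families and five EED candidate families, and the default
#' uncertainty-factor table. Per-stage RNG seeds are derived
#' deterministically from the master `seed` (see `derive_seed` in the
#' sources), so a single integer reproduces the whole run.
#'
#' @param seed master integer seed.
#' @param n_boot parametric-bootstrap iterations per fit.
#' @param n_var,n_unc variability / uncertainty iterations of the MC2D.
#' @param dilution_factors sludge dilution scenario factors (all >= 1).
#' @param uf_table uncertainty-factor table ([default_uf_table()]).
#' @param ssd_families,eed_families candidate family names.
#' @param min_species minimum species count for an SSD fit.
#' @return a list of class `mp_config`.
#' @export
risk_config <- function(seed = 1L, n_boot = 1001L, n_var = 1001L,
                        n_unc = 1001L, dilution_factors = c(1, 17),
                        uf_table = default_uf_table(),
                        ssd_families = c("lognormal", "loglogistic", "burr"),
                        eed_families = mp_families(),
                        min_species = 8L) {
  stopifnot(n_boot >= 1L, n_var >= 1L, n_unc >= 1L,
            all(dilution_factors >= 1),
            all(ssd_families %in% mp_families()),
            all(eed_families %in% mp_families()))
  structure(list(seed = as.integer(seed), n_boot = as.integer(n_boot),
                 n_var = as.integer(n_var), n_unc = as.integer(n_unc),
                 dilution_factors = dilution_factors, uf_table = uf_table,
                 ssd_families = ssd_families, eed_families = eed_families,
                 min_species = as.integer(min_species)),
            class = c("mp_config", "list"))
}
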