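#' Run the full risk-assessment pipeline
#'
#' Orchestrates harmonize -> convert -> SSD -> EEDs -> dilution -> MC2D
#' sweep -> report. Inputs can be in-memory tables (as produced by
#' [gen_full_study()] or the loaders) or CSV file paths.
#'
#' @param toxicity toxicity table (data.frame) or CSV path.
#' @param exposure named list (`sludge`, `sas`, `control`) of exposure
#'   tables (data.frames) or CSV paths.
#' @param config run configuration ([risk_config()]).
#' @param out_dir optional output directory; when given, every result table
#'   is written as CSV plus a JSON run summary and the two figures
#'   (SSD/EED overlay, dilution sweep) as PDFs.
#' @return list of class `mp_run`: `harmonized`, `species`, `ssd`, `eeds`
#'   (named list of `mp_eed`, incl. `diluted_sludge`), `dilution` (ratio and
#'   rounded factor), `risk` (list of `mp_risk`), `tables` (percentiles,
#'   risk, fits, compliance), `config`, `log` (curation mutations).
#' @export
run_pipeline <- function(toxicity, exposure, config = risk_config(),
                         out_dir = NULL) {
  log_lines <- character(0)
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mp("pipeline stage '%s' failed: %s", name, conditionMessage(e),
              class = "mp_stage_error")
    })
  }
  if (is.character(toxicity)) toxicity <- load_toxicity_table(toxicity)
  for (m in c("sludge", "sas", "control")) {
    if (!m %in% names(exposure)) {
      stop_mp("missing exposure input for matrix '%s'", m,
              class = "mp_config_error")
    }
    if (is.character(exposure[[m]])) {
      exposure[[m]] <- load_exposure_table(exposure[[m]], m)
    }
    if (!"matrix" %in% names(exposure[[m]])) exposure[[m]]$matrix <- m
    if (!"concentration" %in% names(exposure[[m]])) {
      exposure[[m]]$concentration <- exposure[[m]]$concentration_nb_per_kg_dw
    }
  }

  harmonized <- stage("harmonize", harmonize_toxicity(
    toxicity, uf_table = config$uf_table))
  note("harmonized %d toxicity entries into %d study x species x particle records",
       nrow(toxicity), nrow(harmonized))
  species <- stage("aggregate_species", aggregate_species(harmonized))
  note("aggregated to %d species sensitivities", nrow(species))

  ssd <- stage("ssd", build_ssd(species, config))
  note("SSD family selected: %s (n_species = %d)", ssd$fit$family,
       ssd$n_species)

  eeds <- list()
  for (m in c("sludge", "sas", "control")) {
    curated <- stage(paste0("curate_", m),
                     curate_exposure(exposure[[m]], note = note))
    eeds[[m]] <- stage(paste0("eed_", m), build_eed(curated, m, config))
    note("EED %s: %s selected on %d entries", m, eeds[[m]]$fit$family,
         eeds[[m]]$n_samples)
  }

  dilution <- stage("dilution", dilution_factor(eeds$sludge, eeds$sas))
  note("sludge-to-SAS dilution ratio %.2f -> realistic factor %d",
       dilution$ratio, dilution$factor)
  realistic <- max(config$dilution_factors)
  eeds$diluted_sludge <- apply_dilution(eeds$sludge, realistic)

  risk <- stage("mc2d", scenario_sweep(
    ssd, eeds[c("sludge", "sas", "control")],
    factors = config$dilution_factors, config = config))

  threshold <- ssd$hc5_upper
  compliance <- do.call(rbind, lapply(names(eeds), function(m) {
    cf <- compliance_fraction(eeds[[m]], threshold)
    data.frame(matrix = m, threshold = threshold,
               compliant_modelled = cf$modelled,
               compliant_empirical = cf$empirical, stringsAsFactors = FALSE)
  }))

  tables <- list(
    harmonized = as.data.frame(harmonized),
    species_sensitivity = as.data.frame(species),
    percentiles = percentile_table(ssd, eeds),
    fits = fits_table(ssd, eeds),
    risk = risk_table(risk),
    compliance = compliance
  )
  run <- structure(list(harmonized = harmonized, species = species, ssd = ssd,
                        eeds = eeds, dilution = dilution, risk = risk,
                        tables = tables, config = config, log = log_lines),
                   class = "mp_run")
  if (!is.null(out_dir)) {
    manifest <- write_results(tables, out_dir, config = unclass(config),
                              seed = config$seed)
    writeLines(log_lines, file.path(out_dir, "curation_log.txt"))
    grDevices::pdf(file.path(out_dir, "ssd_eed_overlay.pdf"), width = 7,
                   height = 5)
    plot_ssd_eed_overlay(ssd, eeds)
    grDevices::dev.off()
    grDevices::pdf(file.path(out_dir, "dilution_sweep.pdf"), width = 7,
                   height = 5)
    plot_dilution_sweep(risk)
    grDevices::dev.off()
    run$manifest <- manifest
  }
  run
}

# Per-study curation of an exposure table: per-site averaging and, where a
# study exceeds the site cap, the percentile collapse. Logged, never silent.
curate_exposure <- function(samples, max_entries = 9L, note = NULL) {
  samples <- as.data.frame(samples)
  out <- lapply(split(samples, factor(samples$study_id,
                                      levels = unique(samples$study_id))),
                function(st) {
    red <- collapse_multisite_study(st, max_entries = max_entries,
                                    seed = 1L + nchar(st$study_id[1L]))
    if (!is.null(note) && nrow(red) < nrow(st)) {
      note("study '%s': %d samples curated to %d entries", st$study_id[1L],
           nrow(st), nrow(red))
    }
    red
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

percentile_table <- function(ssd, eeds) {
  rows <- lapply(names(eeds), function(m) {
    df <- eeds[[m]]$percentiles
    df$dataset <- paste0("eed_", m)
    df$family <- eeds[[m]]$fit$family
    df$empirical_median <- eeds[[m]]$empirical_median
    df
  })
  sdf <- ssd$percentiles
  sdf$dataset <- "ssd"
  sdf$family <- ssd$fit$family
  sdf$empirical_median <- NA_real_
  out <- do.call(rbind, c(rows, list(sdf)))
  out <- out[, c("dataset", "family", "p", "point", "boot_median", "ci_low",
                 "ci_high", "empirical_median")]
  rownames(out) <- NULL
  out
}

fits_table <- function(ssd, eeds) {
  tag <- function(rk, ds) {rk$dataset <- ds; rk}
  out <- do.call(rbind, c(
    list(tag(ssd$ranking, "ssd")),
    lapply(names(eeds), function(m) tag(eeds[[m]]$ranking, paste0("eed_", m)))))
  rownames(out) <- NULL
  out[, c("dataset", "family", "converged", "n_par", "loglik", "aic",
          "selected", "message")]
}

#' @export
print.mp_run <- function(x, ...) {
  cat("<mp_run>\n")
  cat(sprintf("  SSD: %s on %d species; HC5 = %.4g [%.4g; %.4g]\n",
              x$ssd$fit$family, x$ssd$n_species, x$ssd$hc5$boot_median,
              x$ssd$hc5$ci_low, x$ssd$hc5$ci_high))
  cat(sprintf("  dilution ratio %.2f (factor %d)\n", x$dilution$ratio,
              x$dilution$factor))
  print(x$tables$risk[, c("scenario", "factor", "proportion_point",
                          "unc_low", "unc_high", "verdict")],
        row.names = FALSE)
  invisible(x)
}

#' Two-sample comparison of SAS and control concentrations
#'
#' Convenience reproduction of the usual field comparison: a Wilcoxon
#' rank-sum test on the raw concentrations and a two-sample t-test on the
#' log-transformed concentrations. Descriptive only — the risk pipeline
#' does not use it.
#'
#' @param sas,control exposure tables or numeric concentration vectors.
#' @return data.frame with test names, statistics and p-values.
#' @export
compare_groups <- function(sas, control) {
  x <- if (is.data.frame(sas)) sas$concentration else sas
  y <- if (is.data.frame(control)) control$concentration else control
  if (length(x) < 3L || length(y) < 3L) {
    stop_mp("both groups need >= 3 observations", class = "mp_precondition_error")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && x[1] == y[1]) {
    stop_mp("degenerate groups: all values identical", class = "mp_degenerate_error")
  }
  w <- stats::wilcox.test(x, y, exact = FALSE)
  tt <- stats::t.test(log(x[x > 0]), log(y[y > 0]))
  data.frame(test = c("wilcoxon_rank_sum_raw", "t_test_log"),
             statistic = c(unname(w$statistic), unname(tt$statistic)),
             p_value = c(w$p.value, tt$p.value), stringsAsFactors = FALSE)
}
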