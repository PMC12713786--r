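exp_df <- function(conc, study = "s1", sites = NULL, matrix = "sludge") {
  n <- length(conc)
  data.frame(sample_id = sprintf("%s_%03d", study, seq_len(n)),
             study_id = study,
             site_id = sites %||% sprintf("%s_site%03d", study, seq_len(n)),
             matrix = matrix, concentration = conc, stringsAsFactors = FALSE)
}

test_that("multisite collapse: averaging, cap pass-through, 9 percentiles", {
  # 5 sites stay as 5 (after site averaging)
  small <- exp_df(c(10, 20, 30, 40, 50))
  expect_equal(collapse_multisite_study(small)$concentration,
               c(10, 20, 30, 40, 50))
  # repeated samples at one site are averaged first
  rep_site <- exp_df(c(10, 30, 100), sites = c("a", "a", "b"))
  out <- collapse_multisite_study(rep_site)
  expect_equal(out$concentration, c(20, 100))
  # 28 sites collapse to 9 strictly increasing percentile entries
  set.seed(8)
  big <- exp_df(rlnorm(28, 9, 1))
  red <- collapse_multisite_study(big, n_boot = 300, seed = 4)
  expect_equal(nrow(red), 9L)
  expect_true(all(diff(red$concentration) > 0))
  # the middle value is the bootstrap-median 50th percentile ~ exp(9)
  expect_gt(red$concentration[5] / exp(9), 0.5)
  expect_lt(red$concentration[5] / exp(9), 2)
  # bounded by the fitted support (positive, finite)
  expect_true(all(is.finite(red$concentration) & red$concentration > 0))
})

test_that("build_eed selects by AIC over five families and reports percentiles", {
  cfg <- risk_config(seed = 10L, n_boot = 150L)
  set.seed(10)
  x <- exp_df(rlnorm(50, 7, 1.6), matrix = "sas")
  eed <- build_eed(x, "sas", cfg)
  expect_s3_class(eed, "mp_eed")
  expect_equal(eed$n_samples, 50L)
  expect_setequal(eed$ranking$family, mp_families())
  expect_equal(eed$percentiles$p, c(0.05, 0.5, 0.95))
  expect_true(all(diff(eed$percentiles$point) > 0))
  expect_equal(eed$empirical_median, median(x$concentration))
  expect_error(build_eed(exp_df(1:5), "sludge", cfg),
               class = "mp_precondition_error")
})

test_that("heavy-tailed recovery: fitted median tracks a Burr truth", {
  truth_par <- c(shape1 = 0.5, shape2 = 1.5, scale = 2e4)
  true_median <- qburr(0.5, 0.5, 1.5, 2e4)
  set.seed(12)
  meds <- replicate(100, {
    x <- qburr(runif(74), 0.5, 1.5, 2e4)
    sel <- select_by_aic(x, mp_families())
    percentile(sel$fit, 0.5)
  })
  expect_equal(median(meds), true_median, tolerance = 0.3)
})

test_that("dilution factor is the ratio of fitted medians", {
  cfg <- risk_config(seed = 13L, n_boot = 150L)
  set.seed(13)
  sludge <- build_eed(exp_df(rlnorm(74, log(19000), 1.2)), "sludge", cfg)
  sas <- build_eed(exp_df(rlnorm(50, log(1100), 1.2), matrix = "sas"),
                   "sas", cfg)
  d <- dilution_factor(sludge, sas)
  m_sl <- sludge$percentiles$boot_median[sludge$percentiles$p == 0.5]
  m_sa <- sas$percentiles$boot_median[sas$percentiles$p == 0.5]
  expect_equal(d$ratio, m_sl / m_sa)
  expect_equal(d$factor, round(m_sl / m_sa))
  expect_equal(dilution_factor(sludge, sludge)$ratio, 1)
  expect_warning(dilution_factor(sas, sludge), "factor < 1")
})

test_that("dilution acts exactly on the scale parameter for every family", {
  cfg <- risk_config(seed = 14L, n_boot = 60L)
  pars <- list(lognormal = c(meanlog = 9, sdlog = 1.5),
               loglogistic = c(shape = 1.8, scale = 1e4),
               burr = c(shape1 = 0.5, shape2 = 1.5, scale = 9e3),
               weibull = c(shape = 0.6, scale = 400),
               gamma = c(shape = 1.2, scale = 800))
  for (fam in names(pars)) {
    set.seed(15)
    x <- exp_df(family_spec(fam)$rfun(60, pars[[fam]]))
    eed <- build_eed(x, "sludge",
                     risk_config(seed = 14L, n_boot = 60L,
                                 eed_families = fam))
    dil <- apply_dilution(eed, 17)
    for (p in c(0.05, 0.5, 0.95)) {
      expect_equal(percentile(dil$fit, p), percentile(eed$fit, p) / 17,
                   tolerance = 1e-12, info = fam)
    }
    # ensemble draws transformed identically: boot quantiles divide exactly
    expect_equal(dil$percentiles$boot_median,
                 eed$percentiles$boot_median / 17, tolerance = 1e-12)
    # P95/P50 ratio invariant under dilution (scale family property)
    expect_equal(percentile(dil$fit, 0.95) / percentile(dil$fit, 0.5),
                 percentile(eed$fit, 0.95) / percentile(eed$fit, 0.5),
                 tolerance = 1e-9)
    expect_equal(dil$empirical_median, eed$empirical_median / 17)
  }
  eed <- build_eed(exp_df(rlnorm(20, 5, 1)), "sludge",
                   risk_config(n_boot = 30L, eed_families = "lognormal"))
  expect_identical(apply_dilution(eed, 1), eed)
  expect_error(apply_dilution(eed, 0), class = "mp_precondition_error")
})

test_that("compliance fraction is the EED CDF plus an empirical fraction", {
  cfg <- risk_config(seed = 16L, n_boot = 50L, eed_families = "lognormal")
  set.seed(16)
  eed <- build_eed(exp_df(rlnorm(40, 6, 1)), "sas", cfg)
  m <- percentile(eed$fit, 0.5)
  cf <- compliance_fraction(eed, m)
  expect_equal(cf$modelled, 0.5, tolerance = 1e-10)
  expect_true(cf$empirical >= 0 && cf$empirical <= 1)
  # nondecreasing in the threshold, -> 1
  ths <- m * c(0.1, 1, 10, 1e6)
  mods <- vapply(ths, function(t) compliance_fraction(eed, t)$modelled,
                 numeric(1))
  expect_true(all(diff(mods) >= 0))
  expect_equal(mods[4], 1, tolerance = 1e-6)
  expect_error(compliance_fraction(eed, 0), class = "mp_precondition_error")
})
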