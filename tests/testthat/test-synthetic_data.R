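test_that("truth presets encode the stated world geometry", {
  truth <- synthetic_truth()
  expect_equal(qlnorm(0.5, truth$ssd$params[["meanlog"]],
                      truth$ssd$params[["sdlog"]]), 85484, tolerance = 1e-6)
  expect_equal(truth$true_hc5, 145, tolerance = 1e-6)
  # sludge Burr median ~1.9e4, SAS lognormal median ~1.1e3, control ~2.3e2
  expect_equal(qburr(0.5, 0.38, 1.5, 6333), 1.9e4, tolerance = 0.05)
  expect_equal(exp(truth$eed$sas$params[["meanlog"]]), 1106)
  expect_equal(qweibull(0.5, 0.555, 435), 225, tolerance = 0.05)
  # closed-form true proportion for the lognormal matrix
  p_sas <- truth$true_proportion(1, "sas")
  mu <- truth$ssd$params
  oracle <- pnorm((log(1106) - mu[["meanlog"]]) /
                    sqrt(truth$eed$sas$params[["sdlog"]]^2 + mu[["sdlog"]]^2))
  expect_equal(p_sas, oracle, tolerance = 1e-12)
  # brute-force matrix agrees with an independent resampling at the truth
  p_sludge <- truth$true_proportion(1, "sludge", n = 2e5)
  set.seed(99)
  s <- rlnorm(2e5, mu[["meanlog"]], mu[["sdlog"]])
  cc <- qburr(runif(2e5), 0.38, 1.5, 6333)
  expect_equal(p_sludge, mean(cc > s), tolerance = 0.01)
})

test_that("generated toxicity tables pass the loader unchanged", {
  bundle <- gen_toxicity_entries(synthetic_truth(), seed = 3L)
  expect_equal(nrow(bundle$table), 91L)
  expect_equal(nrow(bundle$species), 25L)
  path <- write_tox_csv(bundle$table)
  loaded <- load_toxicity_table(path)   # errors if any row is invalid
  expect_equal(nrow(loaded), 91L)
  expect_null(attr(loaded, "rejected"))
})

test_that("harmonization reverses the generator's UF construction", {
  truth <- synthetic_truth()
  # noiseless, UFs forced to 1, pure number units: exact identity
  b0 <- gen_toxicity_entries(truth, n_species = 10L, n_entries = 20L,
                             seed = 4L, entry_noise_sd = 0,
                             uf_randomize = FALSE, mg_fraction = 0)
  h0 <- aggregate_species(harmonize_toxicity(b0$table))
  m <- match(h0$species_label, b0$species$species_label)
  expect_equal(h0$geomean_noec_equivalent, b0$species$true_mean[m],
               tolerance = 1e-12)
  # with UF randomization and mg/kg mixing: identity up to conversion
  # arithmetic (the divisor is constructed to cancel exactly)
  b1 <- gen_toxicity_entries(truth, n_species = 10L, n_entries = 25L,
                             seed = 5L, entry_noise_sd = 0,
                             uf_randomize = TRUE, mg_fraction = 0.5)
  h1 <- aggregate_species(harmonize_toxicity(b1$table))
  m <- match(h1$species_label, b1$species$species_label)
  expect_equal(h1$geomean_noec_equivalent, b1$species$true_mean[m],
               tolerance = 1e-9)
  # with noise: recovery within the noise scale on the log axis
  b2 <- gen_toxicity_entries(truth, n_species = 25L, seed = 6L)
  h2 <- aggregate_species(harmonize_toxicity(b2$table))
  m <- match(h2$species_label, b2$species$species_label)
  err <- log(h2$geomean_noec_equivalent) - log(b2$species$true_mean[m])
  expect_lt(max(abs(err)), 4 * truth$entry_noise_sd)
})

test_that("exposure generator respects presets, seeds and preconditions", {
  truth <- synthetic_truth()
  for (seed in 1:5) {
    x <- gen_exposure_samples(truth, "sludge", 74L, seed = seed)
    expect_equal(nrow(x), 74L)
    med <- median(x$concentration_nb_per_kg_dw)
    expect_gt(med / 1.9e4, 0.5)
    expect_lt(med / 1.9e4, 2)
  }
  a <- gen_exposure_samples(truth, "control", 23L, seed = 7L)
  b <- gen_exposure_samples(truth, "control", 23L, seed = 7L)
  expect_identical(a, b)
  c2 <- gen_exposure_samples(truth, "control", 23L, seed = 8L)
  expect_false(identical(a$concentration_nb_per_kg_dw,
                         c2$concentration_nb_per_kg_dw))
  expect_error(gen_exposure_samples(truth, "control", 0L),
               class = "mp_precondition_error")
  expect_error(gen_exposure_samples(truth, "seawater", 20L),
               class = "mp_config_error")
})

test_that("two seeds give different tables with identical schemas", {
  t1 <- gen_toxicity_entries(synthetic_truth(), seed = 1L)$table
  t2 <- gen_toxicity_entries(synthetic_truth(), seed = 2L)$table
  expect_identical(names(t1), names(t2))
  expect_false(identical(t1$noec_value, t2$noec_value))
})

test_that("gen_full_study bundles tables and truth targets; floors apply", {
  cfg <- risk_config(seed = 11L)
  b <- gen_full_study(cfg)
  expect_setequal(names(b$exposure), c("sludge", "sas", "control"))
  expect_equal(vapply(b$exposure, nrow, integer(1)),
               c(sludge = 74L, sas = 50L, control = 23L))
  expect_equal(b$targets$true_hc5, 145, tolerance = 1e-6)
  expect_named(b$targets$true_proportion, c("factor_1", "factor_17"))
  expect_error(gen_full_study(cfg, n_species = 1L),
               class = "mp_precondition_error")
})
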