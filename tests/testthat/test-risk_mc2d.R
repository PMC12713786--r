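test_that("MC2D with identical distributions gives one half", {
  ens <- fixed_ensemble("lognormal", c(meanlog = 5, sdlog = 1))
  r <- simulate_proportion_affected(ens, ens, n_var = 1001, n_unc = 5,
                                    seed = 1)
  expect_lt(abs(r$proportion_point - 0.5), 0.03)
})

test_that("MC2D matches the closed-form normal-overlap oracle", {
  ssd <- fixed_ensemble("lognormal", c(meanlog = 6, sdlog = 1))
  eed <- fixed_ensemble("lognormal", c(meanlog = 5, sdlog = 1))
  r <- simulate_proportion_affected(ssd, eed, n_var = 1001, n_unc = 20,
                                    seed = 2)
  expect_lt(abs(r$proportion_point - pnorm(-1 / sqrt(2))), 0.03)
  # oracle also holds under dilution (shifts the exposure meanlog)
  r4 <- simulate_proportion_affected(ssd, eed, factor = 4, n_var = 2001,
                                     n_unc = 20, seed = 3)
  oracle4 <- pnorm((5 - log(4) - 6) / sqrt(2))
  expect_lt(abs(r4$proportion_point - oracle4), 3 / sqrt(2001))
})

test_that("separation limit: exposure far below sensitivity gives ~0", {
  ssd <- fixed_ensemble("lognormal", c(meanlog = 6, sdlog = 1))
  eed <- fixed_ensemble("lognormal", c(meanlog = 6 - log(1e6), sdlog = 1))
  r <- simulate_proportion_affected(ssd, eed, n_var = 1001, n_unc = 5,
                                    seed = 4)
  expect_lt(r$proportion_point, 0.001)
})

test_that("MC2D is deterministic given the seed and bounded", {
  set.seed(20)
  fit_s <- fit_mle(rlnorm(25, 11, 3.5), "lognormal")
  fit_c <- fit_mle(rlnorm(74, 9, 1.5), "lognormal")
  ens_s <- parametric_bootstrap(fit_s, 100, seed = 5)$ensemble
  ens_c <- parametric_bootstrap(fit_c, 100, seed = 6)$ensemble
  r1 <- simulate_proportion_affected(ens_s, ens_c, n_var = 301, n_unc = 101,
                                     seed = 7)
  r2 <- simulate_proportion_affected(ens_s, ens_c, n_var = 301, n_unc = 101,
                                     seed = 7)
  expect_identical(r1$proportions, r2$proportions)
  expect_true(all(r1$proportions >= 0 & r1$proportions <= 1))
  expect_true(r1$unc_low <= r1$proportion_point &&
                r1$proportion_point <= r1$unc_high)
  # shared variability layout also deterministic, same contract
  r3 <- simulate_proportion_affected(ens_s, ens_c, n_var = 301, n_unc = 101,
                                     seed = 7, shared_variability = TRUE)
  expect_true(r3$unc_low <= r3$proportion_point &&
                r3$proportion_point <= r3$unc_high)
  expect_error(simulate_proportion_affected(ens_s, ens_c, factor = 0.5),
               class = "mp_precondition_error")
})

test_that("uncertainty interval narrows as the toxicity sample grows", {
  eed <- fixed_ensemble("lognormal", c(meanlog = 10, sdlog = 1.5))
  widths <- vapply(c(25, 100, 400), function(n) {
    set.seed(30 + n)
    fit <- fit_mle(rlnorm(n, 11, 3.5), "lognormal")
    ens <- parametric_bootstrap(fit, 150, seed = 30 + n)$ensemble
    r <- simulate_proportion_affected(ens, eed, n_var = 501, n_unc = 150,
                                      seed = 31)
    r$unc_high - r$unc_low
  }, numeric(1))
  expect_true(widths[3] < widths[1])
})

test_that("scenario sweep covers factors and extra matrices; verdicts split", {
  ssd <- fixed_ensemble("lognormal", c(meanlog = 11.36, sdlog = 3.88))
  sludge <- fixed_ensemble("burr", c(shape1 = 0.38, shape2 = 1.5,
                                     scale = 6333))
  control <- fixed_ensemble("weibull", c(shape = 0.555, scale = 435))
  cfg <- risk_config(seed = 9L, n_var = 501L, n_unc = 60L)
  res <- scenario_sweep(ssd, list(sludge = sludge, control = control),
                        factors = c(1, 17), config = cfg)
  expect_setequal(names(res),
                  c("worst_case_sludge", "sludge_dilution_17", "control"))
  expect_gte(res$worst_case_sludge$proportion_point,
             res$sludge_dilution_17$proportion_point - 0.05)
  tab <- risk_table(res)
  expect_setequal(names(tab)[1:6],
                  c("scenario", "factor", "proportion_point", "unc_low",
                    "unc_high", "verdict"))
})

test_that("exceedance verdicts partition the interval cases", {
  mk <- function(lo, hi, point = (lo + hi) / 2) {
    structure(list(scenario = "x", factor = 1, proportion_point = point,
                   proportion_mean = point, unc_low = lo, unc_high = hi,
                   n_var = 1L, n_unc = 1L, seed = 1L,
                   proportions = point), class = "mp_risk")
  }
  v <- exceedance_verdict(list(a = mk(0.24, 0.55), b = mk(0.02, 0.17),
                               c = mk(0.001, 0.004)))
  expect_equal(v$verdict, c("exceeds", "intersects", "below"))
})
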