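test_that("closed-form PTA matches the normal-CDF construction", {
  expect_equal(pta_closed_form(0, 93.8), 1)
  expect_equal(pta_closed_form(0, 70), 0)
  expect_equal(pta_closed_form(0.170, 93.8), 0.6510503, tolerance = 1e-6)
  expect_equal(pta_closed_form(0.170, 95), 0.6497229, tolerance = 1e-6)
  # with the target on the lower boundary, half the population falls below it
  omega <- 0.170
  p_above_low <- stats::pnorm(log(80 / 80) / omega)
  expect_equal(p_above_low, 0.5)
  expect_error(pta_closed_form(0.17, 95, c(110, 80)), "low < high")
})

test_that("Monte-Carlo theoretical best agrees with the closed form", {
  res <- theoretical_best_pta(n = 1e5, seed = 11)
  expect_equal(res$monte_carlo, res$closed_form, tolerance = 3 * res$mc_se / res$closed_form)
  res2 <- theoretical_best_pta(n = 1e5, seed = 11)
  expect_identical(res$monte_carlo, res2$monte_carlo)
})

test_that("theoretical-best PTA strictly decreases as omega_CL grows", {
  omegas <- seq(0.05, 0.6, by = 0.05)
  pta <- vapply(omegas, pta_closed_form, numeric(1), target = 93.8)
  expect_true(all(diff(pta) < 0))
})

test_that("with no variability and no binding caps individualized PTA is 1", {
  pop0 <- pop_params(omega_CL = 0)
  coh <- generate_cohort(cohort_spec(n_per_group = c(0, 50, 0)), seed = 3)
  res <- run_pta(cohort = coh, arms = "individualized", pop = pop0,
                 config = sim_config(seed = 3))
  all_row <- res$summary[res$summary$stratum == "all", ]
  expect_equal(all_row$frac_within, 1)
})

test_that("window classification partitions every stratum exactly", {
  res <- run_pta(config = sim_config(n_per_group = 300, seed = 5))
  s <- res$summary[!res$summary$empty, ]
  expect_true(all(abs(s$frac_below + s$frac_within + s$frac_above - 1) < 1e-12))
  counts <- s$n[s$stratum != "all"]
  expect_true(all(counts == 300))
})

test_that("individualized dosing attains the target at least as often as standard", {
  res <- run_pta(arms = c("standard", "individualized"),
                 config = sim_config(n_per_group = 500, seed = 9))
  s <- res$summary
  for (st in c("<2", "2-12", ">12", "all")) {
    expect_gte(s$frac_within[s$arm == "individualized" & s$stratum == st],
               s$frac_within[s$arm == "standard" & s$stratum == st])
  }
})

test_that("uncapped individualized PTA is invariant to the covariate distribution", {
  # dose = target * typical CL cancels typical CL in AUC = dose / CL
  no_caps <- dosing_policy(cap_abs = 1e9, cap_perkg = 1e9)
  cfg <- sim_config(n_per_group = 400, seed = 13)
  coh_a <- generate_cohort(cohort_spec(n_per_group = 400), seed = 101)
  coh_b <- generate_cohort(cohort_spec(n_per_group = 400, cv_weight = 0.2,
                                       cv_creat = 0.3), seed = 202)
  pa <- run_pta(coh_a, "individualized", policy = no_caps, config = cfg)
  pb <- run_pta(coh_b, "individualized", policy = no_caps, config = cfg)
  a <- pa$summary[pa$summary$stratum == "all", "frac_within"]
  b <- pb$summary[pb$summary$stratum == "all", "frac_within"]
  expect_identical(a, b)  # same eta substream, dose cancels clearance
  expect_equal(a, pta_closed_form(0.170, 95), tolerance = 0.05)
})

test_that("an empty stratum is flagged rather than fabricated", {
  coh <- generate_cohort(cohort_spec(n_per_group = c(0, 30, 30)), seed = 2)
  res <- run_pta(cohort = coh, arms = "standard", config = sim_config(seed = 2))
  row <- res$summary[res$summary$stratum == "<2", ]
  expect_true(row$empty)
  expect_true(is.na(row$frac_within))
  expect_equal(row$n, 0L)
})
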