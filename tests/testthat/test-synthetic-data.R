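test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(small_spec(), seed = 4)
  b <- generate_cohort(small_spec(), seed = 4)
  expect_identical(a, b)
  c <- generate_cohort(small_spec(), seed = 5)
  expect_false(identical(a$weight, c$weight))
})

test_that("an all-empty cohort is a valid empty table", {
  coh <- generate_cohort(cohort_spec(n_per_group = 0), seed = 1)
  expect_equal(nrow(coh), 0)
  expect_true(all(c("age", "weight", "height", "creatinine_umol_l", "group")
                  %in% names(coh)))
})

test_that("generated covariates stay inside the pediatric plausibility envelope", {
  coh <- generate_cohort(cohort_spec(n_per_group = 1000), seed = 6)
  expect_equal(nrow(coh), 3000)
  expect_true(all(coh$weight >= 2 & coh$weight <= 120))
  expect_true(all(coh$height >= 0.45 & coh$height <= 2.0))
  egfr <- egfr_schwartz(coh$height, coh$creatinine_umol_l, "umol/L")
  expect_true(all(egfr >= 50 & egfr <= 300))
  expect_true(all(coh$gestational_age == 40))
})

test_that("cohort anthropometry medians increase across age strata", {
  coh <- generate_cohort(cohort_spec(n_per_group = 500), seed = 8)
  med_w <- tapply(coh$weight, coh$group, median)
  med_h <- tapply(coh$height, coh$group, median)
  expect_true(all(diff(med_w) > 0))
  expect_true(all(diff(med_h) > 0))
})

test_that("noise-free TDM simulation reproduces the typical profile exactly", {
  pop0 <- pop_params(omega_CL = 0, omega_V = 0, omega_D1 = 0,
                     sigma_add = 0, sigma_prop = 0)
  coh <- generate_cohort(cohort_spec(n_per_group = c(0, 3, 0)), seed = 10)
  d <- simulate_tdm(coh, tdm_design(occasions = c(1, 3), n_doses = 3),
                    pop = pop0, seed = 10)
  obs <- d[d$EVID == 0, ]
  for (id in unique(obs$ID)) {
    i <- which(coh$id == id)
    p <- list(CL = typical_cl(coh[i, ], pop0), V = typical_v(coh[i, ], pop0),
              D1 = pop0$theta_D1)
    reg <- dose_regimen(10 * coh$weight[i], 24, pop0$theta_D1, n_doses = 3)
    expect_equal(obs$DV[obs$ID == id],
                 pk_concentration(p, reg, obs$TIME[obs$ID == id]),
                 tolerance = 1e-12)
  }
})

test_that("an LLOQ above every concentration censors every observation", {
  coh <- generate_cohort(cohort_spec(n_per_group = c(0, 5, 0)), seed = 12)
  d <- simulate_tdm(coh, tdm_design(lloq = 1e6), seed = 12)
  obs <- d[d$EVID == 0, ]
  expect_true(all(obs$BLQ))
  expect_true(all(is.na(obs$DV)))
})

test_that("BLQ censoring is strict at the limit and safe on empty input", {
  r <- censor_blq(data.frame(DV = c(0.59, 0.60, 2.1)), lloq = 0.6)
  expect_equal(r$BLQ, c(TRUE, FALSE, FALSE))
  expect_true(is.na(r$DV[1]))
  expect_equal(r$DV[2:3], c(0.60, 2.1))
  empty <- censor_blq(data.frame(DV = numeric(0)), 0.6)
  expect_equal(nrow(empty), 0)
})

test_that("default TDM simulation yields a small but nonzero BLQ fraction", {
  coh <- study_cohort(seed = 14)
  d <- simulate_tdm(coh, seed = 14)
  obs <- d[d$EVID == 0, ]
  frac <- mean(obs$BLQ)
  expect_gte(frac, 0)
  expect_lt(frac, 0.2)  # the clinical anchor is of order a few percent
})

test_that("simulated datasets pass the reader validation on round trip", {
  coh <- generate_cohort(cohort_spec(n_per_group = c(2, 2, 2)), seed = 15)
  d <- simulate_tdm(coh, seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  expect_no_warning(write_pk_dataset(d, path))
  d2 <- expect_no_warning(read_pk_dataset(path))
  expect_equal(nrow(d2), nrow(d))
  expect_equal(d2$DV, d$DV, tolerance = 1e-12)
  expect_equal(d2$BLQ, d$BLQ)
})
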