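test_that("postmenstrual age is postnatal weeks plus gestational age", {
  expect_equal(pma_weeks(0, 40), 40)
  expect_equal(pma_weeks(2), 144)
  expect_equal(pma_weeks(13.3), 731.6)
  expect_equal(pma_weeks(0, 28), 28)
  expect_error(pma_weeks(-0.1), "non-negative")
})

test_that("maturation is half-maximal at TM50, bounded and increasing", {
  expect_equal(maturation(47.7), 0.5)
  expect_equal(maturation(144), 0.9771703, tolerance = 1e-6)
  expect_lt(maturation(1e4), 1)
  expect_gt(maturation(1e4), 0.999)
  pma <- seq(25, 1000, length.out = 200)
  m <- maturation(pma)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > 0 & m < 1))
  expect_error(maturation(0), "positive")
})

test_that("modified Schwartz eGFR converts units and refuses unitless input", {
  expect_equal(egfr_schwartz(1.0, 1.0, "mg/dL"), 41.3)
  expect_equal(egfr_schwartz(1.53, 43, "umol/L"), 129.9048, tolerance = 1e-5)
  expect_error(egfr_schwartz(1.53, 43), "unit")
  expect_error(egfr_schwartz(1.53, 43, "mmol/L"), "unknown creatinine unit")
  expect_error(egfr_schwartz(0, 43, "umol/L"), "positive")
})

test_that("creatinine unit conversion round-trips and stays vectorized", {
  x <- c(14, 43, 107)  # spans the observed clinical range
  back <- creatinine_to_umol(creatinine_to_mgdl(x, "umol/L"), "mg/dL")
  expect_equal(back, x, tolerance = 1e-12)
  # vector values with a scalar unit must not collapse (regression)
  expect_equal(creatinine_to_mgdl(x, "umol/L"), x / 88.4)
  expect_equal(length(creatinine_to_mgdl(x, "umol/L")), 3L)
})

test_that("typical clearance reproduces the reference and worked examples", {
  pop <- pop_params()
  expect_equal(signif(typical_cl(reference_patient(), pop), 3), 6.17)
  expect_equal(typical_cl(infant_patient(), pop), 1.579108, tolerance = 1e-5)
  # allometric power law in weight
  p1 <- infant_patient()
  p2 <- p1; p2$weight <- 2 * p1$weight
  expect_equal(typical_cl(p2, pop) / typical_cl(p1, pop), 2^0.663,
               tolerance = 1e-10)
})

test_that("typical volume follows allometric weight scaling", {
  pop <- pop_params()
  expect_equal(typical_v(reference_patient(), pop), 15.5)
  p <- reference_patient(); p$weight <- 43.8
  expect_equal(typical_v(p, pop), 10.93542, tolerance = 1e-5)
  p$weight <- 70 * 2^(1 / 0.744)
  expect_equal(typical_v(p, pop), 31.0, tolerance = 1e-10)
})

test_that("typical clearance is increasing in weight, eGFR and age", {
  pop <- pop_params()
  base <- patient_covariates(age = 4, weight = 16, height = 1.0,
                             creatinine = 30, creatinine_unit = "umol/L")
  for (col in c("weight", "age")) {
    lo <- base; hi <- base
    hi[[col]] <- base[[col]] * 1.3
    expect_gt(typical_cl(hi, pop), typical_cl(lo, pop))
  }
  hi_egfr <- base; hi_egfr$creatinine_umol_l <- 20  # lower creatinine, higher eGFR
  expect_gt(typical_cl(hi_egfr, pop), typical_cl(base, pop))
})

test_that("age strata partition the supported range with 12 in the middle group", {
  g <- age_group(c(0, 1.99, 2, 11.9, 12, 12.01, 19.3))
  expect_equal(as.character(g), c("<2", "<2", "2-12", "2-12", "2-12", ">12", ">12"))
  expect_error(age_group(20), "19.3")
})

test_that("covariate records are validated", {
  expect_error(patient_covariates(1, 10, 0.75, 20), "unit")
  expect_error(patient_covariates(1, -1, 0.75, 20, "umol/L"), "positive")
  expect_error(patient_covariates(25, 70, 1.7, 50, "umol/L"), "19.3")
  expect_error(patient_covariates(1, 10, 0.75, 20, "umol/L",
                                  gestational_age = 20), "22")
  d <- patient_covariates(1, 10, 0.75, 0.3, "mg/dL")
  expect_equal(d$creatinine_umol_l, 0.3 * 88.4)
})
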