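make_obs <- function(blq, values = c(2.1, 1.5, 0.9), interval = 1, id = 1) {
  data.frame(ID = id, TIME = seq_along(blq), EVID = 0,
             DV = ifelse(blq, NA_real_, values[seq_along(blq)]),
             MDV = ifelse(blq, 1L, 0L), BLQ = blq, INTERVAL = interval)
}

test_that("M6 matches independent enumeration on all length-3 BLQ patterns", {
  vals <- c(2.1, 1.5, 0.9)
  for (code in 0:7) {
    blq <- as.logical(bitwAnd(code, c(1, 2, 4)))
    out <- preprocess_m6(make_obs(blq, vals))
    expected <- m6_enumerate(vals, blq)
    expect_equal(out$DV, expected, info = paste("pattern", paste(blq, collapse = "")))
    expect_true(all(out$MDV == 0))
  }
  # the worked example: [2.1, BLQ, BLQ] -> [2.1, 0.3], one record dropped
  out <- preprocess_m6(make_obs(c(FALSE, TRUE, TRUE)))
  expect_equal(out$DV, c(2.1, 0.3))
})

test_that("M6 never alters non-BLQ records, never adds records, resets across intervals", {
  clean <- make_obs(c(FALSE, FALSE, FALSE))
  expect_equal(preprocess_m6(clean)$DV, clean$DV)
  set.seed(31)
  for (r in 1:20) {
    n <- sample(2:8, 1)
    blq <- sample(c(TRUE, FALSE), n, replace = TRUE)
    d <- data.frame(ID = 1, TIME = 1:n, EVID = 0,
                    DV = ifelse(blq, NA_real_, runif(n, 1, 5)),
                    MDV = ifelse(blq, 1L, 0L), BLQ = blq,
                    INTERVAL = sort(sample(1:2, n, replace = TRUE)))
    out <- preprocess_m6(d)
    expect_lte(nrow(out), nrow(d))
    kept_clean <- out[!out$BLQ, "DV"]
    expect_true(all(kept_clean %in% d$DV[!d$BLQ]))
  }
  # a BLQ leading a new interval is a new sequence even after a BLQ run
  d2 <- rbind(make_obs(c(TRUE, TRUE), values = c(1, 1)),
              make_obs(c(TRUE, FALSE), values = c(1, 2.5), interval = 2))
  d2$TIME <- 1:4
  out2 <- preprocess_m6(d2)
  expect_equal(out2$DV, c(0.3, 0.3, 2.5))
  expect_error(preprocess_m6(data.frame(EVID = 0, DV = 1, BLQ = FALSE)),
               "INTERVAL")
})

test_that("with pinned random effects the OFV is the closed-form WLS deviance", {
  pop <- pop_params(theta_CL = 5, theta_V = 18, theta_D1 = 0.5,
                    omega_CL = 0, omega_V = 0, omega_D1 = 0,
                    sigma_add = 0.15, sigma_prop = 0.1)
  reg <- dose_regimen(400, 24, 0.5, n_doses = 1)
  tt <- c(1.5, 6)
  f <- pk_concentration(list(CL = 5, V = 18, D1 = 0.5), reg, tt)
  y <- c(15, 4)
  d <- data.frame(ID = 1, TIME = c(0, tt), EVID = c(1, 0, 0),
                  AMT = c(400, NA, NA), DUR = c(0.5, NA, NA),
                  DV = c(NA, y), MDV = c(1, 0, 0), BLQ = FALSE,
                  INTERVAL = 1, AGE = 10, WT = 70, HT = 1.4, SCR = 40,
                  SCRU = "umol/L", GA = 40)
  res <- objective_function(d, pop, covariates = character(0))
  g <- pop$sigma_add^2 + (pop$sigma_prop * f)^2
  expected <- sum((y - f)^2 / g + log(g)) + length(y) * log(2 * pi)
  expect_equal(res$ofv, expected, tolerance = 1e-8)
})

test_that("duplicating a dataset doubles the OFV", {
  coh <- generate_cohort(cohort_spec(n_per_group = c(0, 4, 0)), seed = 21)
  d <- preprocess_m6(simulate_tdm(coh, tdm_design(occasions = c(1, 2),
                                                  n_doses = 3), seed = 21))
  d2 <- d
  d2$ID <- d2$ID + 1000
  res1 <- objective_function(d)
  res2 <- objective_function(rbind(d, d2))
  expect_equal(res2$ofv, 2 * res1$ofv, tolerance = 1e-8)
})

test_that("near-deterministic data recover the fixed effects within 2%", {
  pop_gen <- pop_params(omega_CL = 0, omega_V = 0, omega_D1 = 0,
                        sigma_add = 0.01, sigma_prop = 0)
  coh <- generate_cohort(cohort_spec(n_per_group = c(2, 8, 10)), seed = 22)
  d <- simulate_tdm(coh, tdm_design(occasions = c(1, 3), n_doses = 3),
                    pop = pop_gen, seed = 22)
  settings <- estimation_settings(
    init = pop_params(theta_CL = 4, theta_V = 25, theta_D1 = 0.6,
                      omega_CL = 0, omega_V = 0, omega_D1 = 0,
                      sigma_add = 0.05, sigma_prop = 0),
    free = c("theta_CL", "theta_V", "theta_D1", "sigma_add"))
  fit <- suppressWarnings(fit_poppk(d, settings))
  expect_equal(fit$estimates$theta_CL, 6.17, tolerance = 0.02)
  expect_equal(fit$estimates$theta_V, 15.5, tolerance = 0.02)
  expect_equal(fit$estimates$theta_D1, 0.801, tolerance = 0.05)
})

test_that("accepted objective values decrease monotonically and true initials are not worse", {
  coh <- generate_cohort(cohort_spec(n_per_group = c(2, 6, 12)), seed = 23)
  d <- preprocess_m6(simulate_tdm(coh, seed = 23))
  fit_perturbed <- suppressWarnings(fit_poppk(d))
  expect_true(all(diff(fit_perturbed$trace) <= 0))
  true_settings <- estimation_settings(init = pop_params())
  fit_true <- suppressWarnings(fit_poppk(d, true_settings))
  expect_true(all(diff(fit_true$trace) <= 0))
  expect_lt(abs(fit_true$ofv - fit_perturbed$ofv), 2)
})

test_that("likelihood-ratio decisions follow the 3.84 threshold strictly", {
  sig <- lrt_covariate_step(100, 96)
  expect_true(sig$significant)
  expect_equal(sig$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(sig$p_value, 4), 0.0455)
  boundary <- lrt_covariate_step(100, 100 - 3.84)
  expect_false(boundary$significant)
  expect_equal(round(boundary$p_value, 4), 0.05)
  none <- lrt_covariate_step(100, 100)
  expect_false(none$significant)
  expect_equal(none$p_value, 1)
  # invariance to a common OFV offset
  shifted <- lrt_covariate_step(1100, 1096)
  expect_equal(shifted$drop, sig$drop)
  expect_equal(shifted$significant, sig$significant)
  expect_warning(lrt_covariate_step(100, 101), "worse")
})

test_that("forward selection with no candidates returns the base model", {
  coh <- generate_cohort(cohort_spec(n_per_group = c(0, 3, 3)), seed = 24)
  d <- preprocess_m6(simulate_tdm(coh, tdm_design(occasions = 1, n_doses = 2),
                                  seed = 24))
  sel <- suppressWarnings(forward_selection(d, list()))
  expect_equal(sel$selected, character(0))
  expect_equal(sel$fit$ofv, sel$base_fit$ofv)
})

test_that("datasets with unhandled BLQ records are refused", {
  coh <- generate_cohort(cohort_spec(n_per_group = c(3, 0, 0)), seed = 25)
  d <- simulate_tdm(coh, tdm_design(lloq = 50), seed = 25)
  expect_error(fit_poppk(d), "preprocess_m6")
})
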