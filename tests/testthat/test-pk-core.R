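test_that("zero dose gives zero concentration everywhere", {
  p <- individual_params(CL = 6.17, V = 15.5, D1 = 0.5)
  r <- dose_regimen(0, 24, 0.5, n_doses = 3)
  expect_equal(pk_concentration(p, r, c(0, 0.5, 3, 50)), rep(0, 4))
})

test_that("closed-form profile matches numeric ODE integration to <0.1%", {
  p <- individual_params(CL = 6.17, V = 15.5, D1 = 0.5)
  tt <- c(0.25, 0.5, 1, 2, 6, 12)
  r1 <- dose_regimen(586.15, 24, 0.5, n_doses = 1)
  a <- pk_concentration(p, r1, tt)
  b <- ode_oracle(tt, 586.15, 6.17, 15.5, 0.5)
  expect_equal(a, b, tolerance = 1e-3)
  # multi-dose superposition against the same oracle
  r3 <- dose_regimen(586.15, 24, 0.5, n_doses = 3)
  tt3 <- c(24.5, 25.5, 48.5, 54)
  expect_equal(pk_concentration(p, r3, tt3),
               ode_oracle(tt3, 586.15, 6.17, 15.5, 0.5, n_doses = 3),
               tolerance = 1e-3)
})

test_that("concentration is non-negative and continuous at end of infusion", {
  p <- individual_params(CL = 6.17, V = 15.5, D1 = 0.5)
  r <- dose_regimen(586.15, 24, 0.5, n_doses = Inf)
  tt <- seq(0, 24, by = 0.05)
  expect_true(all(pk_concentration(p, r, tt) >= 0))
  eps <- 1e-9
  expect_equal(pk_concentration(p, r, 0.5 - eps),
               pk_concentration(p, r, 0.5 + eps), tolerance = 1e-6)
})

test_that("steady-state profile is periodic and multi-dose converges to it", {
  p <- individual_params(CL = 6.17, V = 15.5, D1 = 0.5)
  rss <- dose_regimen(586.15, 24, 0.5, n_doses = Inf)
  tt <- c(0.5, 2, 6, 23)
  expect_equal(pk_concentration(p, rss, tt), pk_concentration(p, rss, tt + 24))
  # half-life ~1.74 h: a full prior day covers >10 half-lives
  r20 <- dose_regimen(586.15, 24, 0.5, n_doses = 20)
  expect_equal(pk_concentration(p, r20, 19 * 24 + tt),
               pk_concentration(p, rss, tt), tolerance = 1e-3)
})

test_that("trapezoidal AUC of the steady-state profile equals dose/CL", {
  p <- individual_params(CL = 6.17, V = 15.5, D1 = 0.5)
  rss <- dose_regimen(586.15, 24, 0.5, n_doses = Inf)
  tg <- seq(0, 24, by = 0.005)
  cs <- pk_concentration(p, rss, tg)
  auc <- sum(diff(tg) * (head(cs, -1) + tail(cs, -1)) / 2)
  expect_equal(auc, auc24_ss(586.15, 6.17), tolerance = 0.005)
})

test_that("steady-state AUC24 is dose over clearance", {
  expect_equal(auc24_ss(0, 6.17), 0)
  expect_equal(auc24_ss(950, 10), 95)
  expect_equal(auc24_ss(586.15, 6.17), 95, tolerance = 1e-10)
  expect_error(auc24_ss(100, 0), "positive")
  expect_error(auc24_ss(-1, 5), "non-negative")
})

test_that("invalid individual parameters are rejected", {
  expect_error(individual_params(CL = 0, V = 15.5), "positive")
  expect_error(individual_params(CL = 6, V = -2), "positive")
  r <- dose_regimen(100)
  expect_error(pk_concentration(list(CL = -1, V = 10), r, 1), "positive")
})

test_that("individual sampling honors omegas, seeds and the lognormal spread", {
  pop0 <- pop_params(omega_CL = 0, omega_V = 0, omega_D1 = 0)
  ind <- sample_individual(pop0, typical_CL = 6.17, typical_V = 15.5)
  expect_equal(ind$CL, 6.17)
  expect_equal(ind$V, 15.5)
  pop <- pop_params()
  set.seed(42); a <- sample_individual(pop, 6.17, 15.5, n = 10)
  set.seed(42); b <- sample_individual(pop, 6.17, 15.5, n = 10)
  expect_identical(a, b)
  set.seed(7)
  draws <- sample_individual(pop, 6.17, 15.5, n = 1e5)
  expect_equal(sd(log(draws$CL / 6.17)), 0.170, tolerance = 0.002 / 0.170)
})
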