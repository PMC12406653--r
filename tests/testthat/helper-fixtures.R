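# Shared fixtures, built in code at test time.

# the 70 kg / eGFR 127.3 / fully matured reference individual
reference_patient <- function() {
  patient_covariates(
    age = 18, weight = 70, height = 1.75,
    creatinine = 41.3 * 1.75 / 127.3 * 88.4,  # puts Schwartz eGFR at exactly 127.3
    creatinine_unit = "umol/L"
  )
}

# the 1-year-old worked example
infant_patient <- function() {
  patient_covariates(age = 1, weight = 10, height = 0.75,
                     creatinine = 20, creatinine_unit = "umol/L")
}

# small cohort spec for fast simulation tests
small_spec <- function(n = 50) cohort_spec(n_per_group = n)

# study-like estimation cohort: clinical TDM population with a wide renal
# function spread (eGFR spanning roughly 50-270 mL/min), age mix like a CF
# TDM case series (10% < 2 y, 30% 2-12 y, 60% > 12 y of 63 subjects)
study_cohort <- function(seed) {
  generate_cohort(
    cohort_spec(n_per_group = c(7, 19, 37), cv_creat = 0.35,
                creat_band = c(0.35, 2.6)),
    seed = seed
  )
}

# numeric ODE solution of the one-compartment infusion model (independent
# oracle for the closed-form superposition)
ode_oracle <- function(times, dose, CL, V, D1, n_doses = 1, tau = 24) {
  rate_fun <- function(t) {
    r <- 0
    for (i in seq_len(n_doses)) {
      s <- (i - 1) * tau
      if (t >= s && t < s + D1) r <- r + dose / D1
    }
    r
  }
  f <- function(t, y, p) list(rate_fun(t) / V - CL / V * y)
  grid <- sort(unique(c(times, seq(0, max(times), by = 0.01))))
  out <- deSolve::ode(c(0), grid, f, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  stats::approx(out[, 1], out[, 2], xout = times)$y
}

# independent enumeration oracle for the M6 rule: within one ordered vector
# of BLQ flags, keep the first of each consecutive TRUE run (imputed at
# lloq/2), drop the rest, pass non-BLQ through unchanged
m6_enumerate <- function(values, blq, lloq = 0.6) {
  out <- numeric(0)
  in_run <- FALSE
  for (i in seq_along(blq)) {
    if (blq[i]) {
      if (!in_run) out <- c(out, lloq / 2)
      in_run <- TRUE
    } else {
      out <- c(out, values[i])
      in_run <- FALSE
    }
  }
  out
}
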