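#' Individual PK parameters
#'
#' Individual-level clearance, volume and infusion duration obtained by
#' applying lognormal between-subject random effects to the typical values:
#' `CL = typical_CL * exp(eta_CL)` and likewise for V and D1.
#'
#' @param CL Clearance (L/h).
#' @param V Volume of distribution (L).
#' @param D1 Infusion duration (h).
#' @param eta_CL,eta_V,eta_D1 Realized random effects (log scale).
#' @return An object of class `individual_params`.
#' @export
individual_params <- function(CL, V, D1 = 0.5,
                              eta_CL = 0, eta_V = 0, eta_D1 = 0) {
  if (!all(is.finite(c(CL, V, D1))) || CL <= 0 || V <= 0 || D1 <= 0) {
    stop("individual_params: CL, V and D1 must be positive and finite",
         call. = FALSE)
  }
  structure(list(CL = CL, V = V, D1 = D1,
                 eta_CL = eta_CL, eta_V = eta_V, eta_D1 = eta_D1),
            class = "individual_params")
}

#' Sample individual parameters from the population distribution
#'
#' Draws independent zero-mean normal random effects with the population SDs
#' and forms individual parameters multiplicatively
#' (`CL = typical_CL * exp(eta_CL)`, etc.). The omega matrix is diagonal.
#'
#' @param pop A [pop_params()] object supplying `omega_CL`, `omega_V`,
#'   `omega_D1`.
#' @param typical_CL,typical_V Typical (covariate-predicted) clearance and
#'   volume for this subject.
#' @param typical_D1 Typical infusion duration (h); defaults to the nominal
#'   0.5 h used for prospective simulation.
#' @param n Number of subjects to draw.
#' @return For `n = 1` an [individual_params()] object; otherwise a data.frame
#'   with columns `CL`, `V`, `D1`, `eta_CL`, `eta_V`, `eta_D1`.
#'
#' @details Reproducibility is controlled through R's RNG: call `set.seed()`
#'   before sampling, as elsewhere in the package.
#' @export
sample_individual <- function(pop, typical_CL, typical_V, typical_D1 = 0.5,
                              n = 1) {
  eta_CL <- stats::rnorm(n, 0, pop$omega_CL)
  eta_V <- stats::rnorm(n, 0, pop$omega_V)
  eta_D1 <- stats::rnorm(n, 0, pop$omega_D1)
  if (n == 1) {
    individual_params(CL = typical_CL * exp(eta_CL),
                      V = typical_V * exp(eta_V),
                      D1 = typical_D1 * exp(eta_D1),
                      eta_CL = eta_CL, eta_V = eta_V, eta_D1 = eta_D1)
  } else {
    data.frame(CL = typical_CL * exp(eta_CL),
               V = typical_V * exp(eta_V),
               D1 = typical_D1 * exp(eta_D1),
               eta_CL = eta_CL, eta_V = eta_V, eta_D1 = eta_D1)
  }
}

# Single-dose zero-order infusion / first-order elimination concentration at
# time `td` after the START of one infusion (vectorized over td).
.conc_one_dose <- function(td, dose, CL, V, D1) {
  k <- CL / V
  R0 <- dose / D1                      # infusion rate, mg/h
  out <- numeric(length(td))
  during <- td >= 0 & td <= D1
  after <- td > D1
  out[during] <- R0 / CL * (1 - exp(-k * td[during]))
  out[after] <- R0 / CL * (1 - exp(-k * D1)) * exp(-k * (td[after] - D1))
  out
}

#' Concentration-time profile of the one-compartment infusion model
#'
#' Closed-form serum concentration under repeated zero-order infusions with
#' first-order elimination. Multiple doses are handled by superposition; the
#' steady-state mode (`n_doses = Inf` in the regimen) applies the standard
#' accumulation factor `1 / (1 - exp(-k * tau))` to a single within-interval
#' profile, so `t` is then interpreted modulo the dosing interval.
#'
#' @param params An [individual_params()] object (or any list with positive
#'   `CL`, `V` and optionally `D1`).
#' @param regimen A [dose_regimen()] object. The regimen's
#'   `infusion_duration` is used unless `params$D1` is non-null, in which case
#'   the individual duration takes precedence.
#' @param t Times (h) since the start of the first infusion; vectorized.
#' @return Concentrations in mg/L at each `t`.
#' @examples
#' p <- individual_params(CL = 6.17, V = 15.5, D1 = 0.5)
#' r <- dose_regimen(dose = 586.15, tau = 24, infusion_duration = 0.5)
#' pk_concentration(p, r, t = c(0.5, 2, 6, 24))
#' @export
pk_concentration <- function(params, regimen, t) {
  if (is.null(params$CL) || is.null(params$V) ||
      !is.finite(params$CL) || !is.finite(params$V) ||
      params$CL <= 0 || params$V <= 0) {
    stop("pk_concentration: CL and V must be positive and finite", call. = FALSE)
  }
  if (any(t < 0)) stop("pk_concentration: t must be non-negative", call. = FALSE)
  D1 <- if (!is.null(params$D1)) params$D1 else regimen$infusion_duration
  if (regimen$dose == 0) return(numeric(length(t)) )
  CL <- params$CL; V <- params$V
  k <- CL / V
  tau <- regimen$tau
  if (is.infinite(regimen$n_doses)) {
    # steady state: within-interval time, accumulation over an infinite train
    tw <- t %% tau
    acc <- 1 / (1 - exp(-k * tau))
    R0 <- regimen$dose / D1
    out <- numeric(length(tw))
    during <- tw <= D1
    # during infusion: current (partial) infusion plus fully decayed prior doses
    out[during] <- R0 / CL * (1 - exp(-k * tw[during])) +
      R0 / CL * (1 - exp(-k * D1)) * exp(-k * (tw[during] - D1 + tau)) * acc
    tw_a <- tw[!during]
    out[!during] <- R0 / CL * (1 - exp(-k * D1)) * exp(-k * (tw_a - D1)) * acc
    out
  } else {
    dose_times <- (seq_len(regimen$n_doses) - 1) * tau
    out <- numeric(length(t))
    for (s in dose_times) {
      idx <- t >= s
      out[idx] <- out[idx] + .conc_one_dose(t[idx] - s, regimen$dose, CL, V, D1)
    }
    out
  }
}

#' Steady-state AUC over 24 hours
#'
#' At steady state with once-daily dosing the area under the concentration-time
#' curve over one interval equals the daily dose divided by clearance.
#'
#' @param dose Daily dose (mg).
#' @param CL Clearance (L/h), positive.
#' @return AUC24 at steady state (mg·h/L): `dose / CL`.
#' @examples
#' auc24_ss(586.15, 6.17)   # 95 mg.h/L, the individualized target
#' @export
auc24_ss <- function(dose, CL) {
  if (any(!is.finite(CL)) || any(CL <= 0)) {
    stop("auc24_ss: CL must be positive and finite", call. = FALSE)
  }
  if (any(dose < 0)) stop("auc24_ss: dose must be non-negative", call. = FALSE)
  dose / CL
}
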