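#' Population pharmacokinetic parameters
#'
#' Constructs the parameter set of the final one-compartment tobramycin model:
#' fixed effects (typical clearance, volume, infusion duration), covariate
#' exponents (allometric weight scaling, eGFR power, renal maturation Hill
#' function), lognormal between-subject variability standard deviations, and
#' combined additive + proportional residual error. Defaults are the final
#' model estimates for a 70 kg reference individual with an eGFR of
#' 127.3 mL/min and fully matured renal function.
#'
#' @param theta_CL Typical clearance (L/h) at the reference covariates.
#' @param theta_V Typical volume of distribution (L) at the reference weight.
#' @param theta_D1 Typical infusion duration (h) as fitted from observed data;
#'   prospective simulation normally uses the nominal duration instead (see
#'   [dose_regimen()]).
#' @param exp_WT_CL Allometric exponent of weight on clearance.
#' @param exp_WT_V Allometric exponent of weight on volume.
#' @param exp_eGFR_CL Power exponent of eGFR on clearance (fixed, not
#'   re-estimated by default).
#' @param hill Hill coefficient of the renal maturation function.
#' @param tm50 Postmenstrual age (weeks) at half-maximal renal maturation.
#' @param ref_WT Reference weight (kg).
#' @param ref_eGFR Reference eGFR (mL/min).
#' @param omega_CL,omega_V,omega_D1 Standard deviations of the lognormal
#'   between-subject random effects (log scale).
#' @param sigma_add Additive residual error SD (mg/L).
#' @param sigma_prop Proportional residual error SD (fraction).
#'
#' @return An object of class `pop_params` (a named list).
#' @examples
#' p <- pop_params()
#' p$theta_CL  # 6.17 L/h
#' @export
pop_params <- function(theta_CL = 6.17,
                       theta_V = 15.5,
                       theta_D1 = 0.801,
                       exp_WT_CL = 0.663,
                       exp_WT_V = 0.744,
                       exp_eGFR_CL = 0.4,
                       hill = 3.4,
                       tm50 = 47.7,
                       ref_WT = 70,
                       ref_eGFR = 127.3,
                       omega_CL = 0.170,
                       omega_V = 0.173,
                       omega_D1 = 0.404,
                       sigma_add = 0.173,
                       sigma_prop = 0.103) {
  p <- list(
    theta_CL = theta_CL, theta_V = theta_V, theta_D1 = theta_D1,
    exp_WT_CL = exp_WT_CL, exp_WT_V = exp_WT_V, exp_eGFR_CL = exp_eGFR_CL,
    hill = hill, tm50 = tm50, ref_WT = ref_WT, ref_eGFR = ref_eGFR,
    omega_CL = omega_CL, omega_V = omega_V, omega_D1 = omega_D1,
    sigma_add = sigma_add, sigma_prop = sigma_prop
  )
  strict_pos <- c("theta_CL", "theta_V", "theta_D1", "hill", "tm50",
                  "ref_WT", "ref_eGFR")
  for (nm in strict_pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("pop_params: '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  nonneg <- c("exp_WT_CL", "exp_WT_V", "exp_eGFR_CL",
              "omega_CL", "omega_V", "omega_D1", "sigma_add", "sigma_prop")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("pop_params: '", nm, "' must be a single non-negative finite number",
           call. = FALSE)
    }
  }
  structure(p, class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (one-compartment IV infusion)\n")
  cat(sprintf("  CL %.3g L/h | V %.3g L | D1 %.3g h  (reference %g kg, eGFR %g mL/min)\n",
              x$theta_CL, x$theta_V, x$theta_D1, x$ref_WT, x$ref_eGFR))
  cat(sprintf("  covariate exponents: WT->CL %.3g, WT->V %.3g, eGFR->CL %.3g; maturation Hill %.3g, TM50 %.3g wk\n",
              x$exp_WT_CL, x$exp_WT_V, x$exp_eGFR_CL, x$hill, x$tm50))
  cat(sprintf("  BSV (SD, log scale): CL %.3g, V %.3g, D1 %.3g\n",
              x$omega_CL, x$omega_V, x$omega_D1))
  cat(sprintf("  residual error: additive %.3g mg/L, proportional %.3g\n",
              x$sigma_add, x$sigma_prop))
  invisible(x)
}

#' Dosing policy
#'
#' Bundles the constants of the once-daily dosing rules: the AUC24 target of
#' the individualized rule, the institutional dose caps (absolute and per-kg,
#' the lower of which applies), and the standard weight-based dose.
#'
#' @param target_auc AUC24 target (mg·h/L) of the individualized rule.
#' @param cap_abs Absolute daily dose cap (mg).
#' @param cap_perkg Per-kilogram daily dose cap (mg/kg).
#' @param standard_perkg Standard daily dose (mg/kg).
#' @param window_low,window_high Therapeutic AUC24 window bounds (mg·h/L), used
#'   only to flag a target outside the evaluation window.
#'
#' @return An object of class `dosing_policy`.
#' @examples
#' dosing_policy()          # target 95, caps 850 mg / 16 mg/kg, standard 10 mg/kg
#' @export
dosing_policy <- function(target_auc = 95, cap_abs = 850, cap_perkg = 16,
                          standard_perkg = 10,
                          window_low = 80, window_high = 110) {
  vals <- c(target_auc = target_auc, cap_abs = cap_abs, cap_perkg = cap_perkg,
            standard_perkg = standard_perkg,
            window_low = window_low, window_high = window_high)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("dosing_policy: all values must be positive and finite", call. = FALSE)
  }
  if (window_low >= window_high) {
    stop("dosing_policy: window_low must be below window_high", call. = FALSE)
  }
  if (target_auc < window_low || target_auc > window_high) {
    warning("dosing_policy: target_auc ", target_auc,
            " lies outside the evaluation window [", window_low, ", ",
            window_high, "]", call. = FALSE)
  }
  structure(as.list(vals), class = "dosing_policy")
}

#' Dose regimen
#'
#' A once- (or fixed-interval) daily zero-order infusion regimen.
#'
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (h).
#' @param infusion_duration Infusion duration (h); the nominal duration is
#'   0.5 h. The fitted duration (0.801 h) is only relevant when reproducing the
#'   estimation model.
#' @param n_doses Number of doses administered, or `Inf` for steady state.
#'
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose, tau = 24, infusion_duration = 0.5,
                         n_doses = Inf) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("dose_regimen: dose must be a single non-negative number", call. = FALSE)
  }
  if (!is.finite(tau) || tau <= 0) stop("dose_regimen: tau must be positive", call. = FALSE)
  if (!is.finite(infusion_duration) || infusion_duration <= 0 ||
      infusion_duration > tau) {
    stop("dose_regimen: infusion_duration must lie in (0, tau]", call. = FALSE)
  }
  if (!(is.infinite(n_doses) || (n_doses == floor(n_doses) && n_doses >= 1))) {
    stop("dose_regimen: n_doses must be a positive integer or Inf", call. = FALSE)
  }
  structure(list(dose = dose, tau = tau,
                 infusion_duration = infusion_duration, n_doses = n_doses),
            class = "dose_regimen")
}
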