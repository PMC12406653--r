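#' Individualized AUC-targeted daily dose
#'
#' Computes the once-daily dose targeting the policy's steady-state AUC24 on
#' the patient's typical (covariate-predicted) clearance:
#' `dose = target_auc * CL`, capped at the lower of the absolute cap and the
#' per-kilogram cap. The binding cap, if any, is recorded.
#'
#' @param typical_CL Typical clearance (L/h), positive; vectorized.
#' @param weight Body weight (kg), positive; vectorized.
#' @param policy A [dosing_policy()] object.
#' @param round_to Optional rounding increment in mg (e.g. 10 for clinical
#'   realism); `NULL` (default) leaves doses unrounded.
#' @return A data.frame of class `dose_recommendation` with columns `dose`
#'   (mg), `dose_perkg` (mg/kg), `cap_applied` (`"none"`, `"absolute"` or
#'   `"per-kg"`) and `predicted_auc` (mg·h/L, `dose / typical_CL`).
#' @examples
#' optimal_dose(6.17, 70)    # 586.15 mg, 8.37 mg/kg, no cap, AUC 95
#' optimal_dose(10, 40)      # per-kg cap: 640 mg
#' @export
optimal_dose <- function(typical_CL, weight, policy = dosing_policy(),
                         round_to = NULL) {
  if (any(!is.finite(typical_CL)) || any(typical_CL <= 0)) {
    stop("optimal_dose: typical_CL must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("optimal_dose: weight must be positive and finite", call. = FALSE)
  }
  n <- max(length(typical_CL), length(weight))
  typical_CL <- rep_len(typical_CL, n)
  weight <- rep_len(weight, n)
  uncapped <- policy$target_auc * typical_CL
  cap_kg <- policy$cap_perkg * weight
  dose <- pmin(uncapped, policy$cap_abs, cap_kg)
  cap_applied <- rep("none", n)
  # when both caps tie below the uncapped dose, report the per-kg cap
  cap_applied[dose < uncapped & dose == policy$cap_abs & dose < cap_kg] <- "absolute"
  cap_applied[dose < uncapped & dose == cap_kg] <- "per-kg"
  if (!is.null(round_to)) dose <- round(dose / round_to) * round_to
  structure(data.frame(dose = dose,
                       dose_perkg = dose / weight,
                       cap_applied = cap_applied,
                       predicted_auc = dose / typical_CL),
            class = c("dose_recommendation", "data.frame"))
}

#' Standard weight-based daily dose
#'
#' The conventional 10 mg/kg once-daily regimen. Uncapped by default,
#' mirroring fixed weight-based dosing practice; caps can be switched on.
#'
#' @param weight Body weight (kg), positive; vectorized.
#' @param policy A [dosing_policy()] object supplying `standard_perkg`.
#' @param apply_caps Apply the policy caps to the standard dose as well?
#'   Default `FALSE`.
#' @return A `dose_recommendation` data.frame (see [optimal_dose()]);
#'   `predicted_auc` is `NA` since no clearance estimate is involved.
#' @examples
#' standard_dose(43.8)   # 438 mg
#' @export
standard_dose <- function(weight, policy = dosing_policy(), apply_caps = FALSE) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("standard_dose: weight must be positive and finite", call. = FALSE)
  }
  dose <- policy$standard_perkg * weight
  cap_applied <- rep("none", length(weight))
  if (apply_caps) {
    capped <- pmin(dose, policy$cap_abs, policy$cap_perkg * weight)
    cap_applied[capped < dose & capped == policy$cap_abs] <- "absolute"
    cap_applied[capped < dose & capped == policy$cap_perkg * weight] <- "per-kg"
    dose <- capped
  }
  structure(data.frame(dose = dose,
                       dose_perkg = dose / weight,
                       cap_applied = cap_applied,
                       predicted_auc = NA_real_),
            class = c("dose_recommendation", "data.frame"))
}
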