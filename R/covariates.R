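#' Patient covariates
#'
#' Validated covariate record(s) driving the clearance and volume model. All
#' arguments are vectorized; scalar arguments recycle.
#'
#' @param age Postnatal age (years), supported range 0 to 19.3.
#' @param weight Body weight (kg).
#' @param height Height (m).
#' @param creatinine Serum creatinine value(s); the unit must be declared.
#' @param creatinine_unit `"umol/L"` or `"mg/dL"`. No default at the value
#'   level would be safe, but the *unit tag* itself is mandatory: creatinine
#'   without a declared unit is an error, never guessed.
#' @param gestational_age Gestational age at birth (weeks); assumed 40 when
#'   not otherwise stated.
#' @param sex Optional label, carried through but unused by the model.
#'
#' @return A data.frame of class `patient_covariates` with columns
#'   `age`, `weight`, `height`, `creatinine_umol_l`, `gestational_age`, `sex`.
#'   Creatinine is stored internally in µmol/L.
#' @examples
#' patient_covariates(age = 1, weight = 10, height = 0.75,
#'                    creatinine = 20, creatinine_unit = "umol/L")
#' @export
patient_covariates <- function(age, weight, height, creatinine,
                               creatinine_unit, gestational_age = 40,
                               sex = NA_character_) {
  if (missing(creatinine_unit) || is.null(creatinine_unit) ||
      any(is.na(creatinine_unit))) {
    stop("patient_covariates: creatinine_unit must be declared ",
         "('umol/L' or 'mg/dL'); units are never guessed", call. = FALSE)
  }
  n <- max(length(age), length(weight), length(height), length(creatinine))
  d <- data.frame(
    age = rep_len(as.numeric(age), n),
    weight = rep_len(as.numeric(weight), n),
    height = rep_len(as.numeric(height), n),
    creatinine_umol_l = creatinine_to_umol(
      rep_len(as.numeric(creatinine), n), rep_len(creatinine_unit, n)),
    gestational_age = rep_len(as.numeric(gestational_age), n),
    sex = rep_len(as.character(sex), n)
  )
  if (any(d$age < 0 | d$age > 19.3)) {
    stop("patient_covariates: age must lie in [0, 19.3] years (the supported population)",
         call. = FALSE)
  }
  if (any(d$weight <= 0) || any(d$height <= 0) || any(d$creatinine_umol_l <= 0)) {
    stop("patient_covariates: weight, height and creatinine must be positive",
         call. = FALSE)
  }
  if (any(d$gestational_age < 22 | d$gestational_age > 44)) {
    stop("patient_covariates: gestational_age must lie in [22, 44] weeks",
         call. = FALSE)
  }
  class(d) <- c("patient_covariates", "data.frame")
  d
}

# 1 mg/dL creatinine = 88.4 umol/L (molar mass conversion)
.CREAT_UMOL_PER_MGDL <- 88.4

normalize_creat_unit <- function(unit) {
  u <- gsub("[^a-z]", "", tolower(as.character(unit)))
  out <- ifelse(u %in% c("umoll", "mumoll", "micromoll"), "umol/L",
         ifelse(u %in% c("mgdl"), "mg/dL", NA_character_))
  if (any(is.na(out))) {
    stop("unknown creatinine unit '", paste(unique(unit[is.na(out)]), collapse = "', '"),
         "'; expected 'umol/L' or 'mg/dL'", call. = FALSE)
  }
  out
}

#' Creatinine unit conversion
#'
#' @param value Creatinine value(s).
#' @param unit Unit of `value`: `"umol/L"` or `"mg/dL"` (vectorized).
#' @return `creatinine_to_umol()` returns µmol/L; `creatinine_to_mgdl()`
#'   returns mg/dL.
#' @export
creatinine_to_umol <- function(value, unit) {
  u <- rep_len(normalize_creat_unit(unit), length(value))
  ifelse(u == "umol/L", value, value * .CREAT_UMOL_PER_MGDL)
}

#' @rdname creatinine_to_umol
#' @export
creatinine_to_mgdl <- function(value, unit) {
  u <- rep_len(normalize_creat_unit(unit), length(value))
  ifelse(u == "mg/dL", value, value / .CREAT_UMOL_PER_MGDL)
}

#' Postmenstrual age
#'
#' Postnatal age plus gestational age, on the weekly time axis of the renal
#' maturation function.
#'
#' @param age Postnatal age (years).
#' @param gestational_age Gestational age (weeks); default 40 (term birth).
#' @return Postmenstrual age in weeks: `age * 52 + gestational_age`.
#' @examples
#' pma_weeks(2)          # 144
#' pma_weeks(0, 28)      # a preterm neonate
#' @export
pma_weeks <- function(age, gestational_age = 40) {
  if (any(age < 0)) stop("pma_weeks: age must be non-negative", call. = FALSE)
  age * 52 + gestational_age
}

#' Renal maturation fraction
#'
#' Sigmoid Hill function of postmenstrual age describing the maturation of
#' glomerular filtration; reaches one-half at `tm50` weeks and approaches 1 in
#' fully matured individuals.
#'
#' @param pma Postmenstrual age (weeks), positive.
#' @param hill Hill coefficient (default 3.4).
#' @param tm50 Half-maximal maturation age (weeks PMA, default 47.7).
#' @return Maturation fraction in (0, 1).
#' @examples
#' maturation(47.7)   # 0.5 by construction
#' maturation(144)    # ~0.977: near-adult GFR by age 2
#' @export
maturation <- function(pma, hill = 3.4, tm50 = 47.7) {
  if (any(pma <= 0)) stop("maturation: pma must be positive", call. = FALSE)
  r <- (pma / tm50)^hill
  r / (1 + r)
}

#' Estimated GFR (modified Schwartz)
#'
#' Bedside Schwartz estimate `41.3 * height / creatinine` with height in metres
#' and creatinine in mg/dL. Creatinine supplied in µmol/L is converted
#' (÷ 88.4); the unit must always be declared.
#'
#' @param height Height (m).
#' @param creatinine Serum creatinine value(s).
#' @param creatinine_unit `"umol/L"` or `"mg/dL"`; mandatory.
#' @param k Schwartz constant (default 41.3 for height in metres).
#' @return eGFR in mL/min (per 1.73 m2 by convention of the formula).
#' @examples
#' egfr_schwartz(1.53, 43, "umol/L")   # ~129.9 mL/min
#' @export
egfr_schwartz <- function(height, creatinine, creatinine_unit, k = 41.3) {
  if (missing(creatinine_unit)) {
    stop("egfr_schwartz: creatinine_unit must be declared ('umol/L' or 'mg/dL')",
         call. = FALSE)
  }
  if (any(height <= 0) || any(creatinine <= 0)) {
    stop("egfr_schwartz: height and creatinine must be positive", call. = FALSE)
  }
  cr_mgdl <- creatinine_to_mgdl(creatinine, creatinine_unit)
  k * height / cr_mgdl
}

#' Typical (population-predicted) clearance and volume
#'
#' `typical_cl()` evaluates the final covariate model for clearance:
#' allometric weight scaling, renal maturation on the postmenstrual-age axis,
#' and eGFR (modified Schwartz) standardized to the reference value.
#' `typical_v()` applies allometric weight scaling to the typical volume.
#' Both accept a `patient_covariates` data.frame and are vectorized over rows.
#'
#' @param cov A [patient_covariates()] data.frame.
#' @param pop A [pop_params()] object.
#' @return Clearance in L/h (`typical_cl`) or volume in L (`typical_v`),
#'   one value per covariate row.
#' @examples
#' ref <- patient_covariates(age = 18, weight = 70, height = 1.75,
#'                           creatinine = 41.3 * 1.75 / 127.3 * 88.4,
#'                           creatinine_unit = "umol/L")
#' typical_cl(ref, pop_params())  # ~6.17 L/h at the reference covariates
#' typical_v(ref, pop_params())   # 15.5 L at 70 kg
#' @export
typical_cl <- function(cov, pop = pop_params()) {
  stopifnot(inherits(cov, "data.frame"))
  pma <- pma_weeks(cov$age, cov$gestational_age)
  egfr <- egfr_schwartz(cov$height, cov$creatinine_umol_l, "umol/L")
  pop$theta_CL *
    maturation(pma, pop$hill, pop$tm50) *
    (cov$weight / pop$ref_WT)^pop$exp_WT_CL *
    (egfr / pop$ref_eGFR)^pop$exp_eGFR_CL
}

#' @rdname typical_cl
#' @export
typical_v <- function(cov, pop = pop_params()) {
  stopifnot(inherits(cov, "data.frame"))
  if (any(cov$weight <= 0)) stop("typical_v: weight must be positive", call. = FALSE)
  pop$theta_V * (cov$weight / pop$ref_WT)^pop$exp_WT_V
}

#' Age-group stratification
#'
#' Partition of the supported age range into the three reporting strata:
#' `[0, 2)` ("<2"), `[2, 12]` ("2-12") and `(12, 19.3]` (">12"). Age exactly
#' 12 belongs to the middle group.
#'
#' @param age Age in years.
#' @return A factor with levels `"<2"`, `"2-12"`, `">12"`.
#' @examples
#' age_group(c(0.5, 2, 12, 12.01))
#' @export
age_group <- function(age) {
  if (any(age < 0 | age > 19.3)) {
    stop("age_group: age must lie in [0, 19.3]", call. = FALSE)
  }
  cut(age, breaks = c(-Inf, 2, 12, Inf), labels = c("<2", "2-12", ">12"),
      right = FALSE, include.lowest = TRUE) -> g
  # cut(right = FALSE) puts 12 in [12, Inf); move it to the middle stratum
  g[age == 12] <- "2-12"
  g
}
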