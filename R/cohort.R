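# Pediatric reference medians used by the virtual-cohort generator.
# Anthropometry: sex-pooled median weight (kg) and height/length (m) by age,
# interpolated from standard growth-reference tables (WHO 0-2 y, CDC 2-20 y).
# Creatinine: age-median serum creatinine (umol/L) consistent with normal
# renal function in childhood (rising with muscle mass from infancy to
# adolescence).
.growth_ref <- data.frame(
  age = c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10,
          11, 12, 13, 14, 15, 16, 17, 18, 19.3),
  weight = c(4.5, 6.0, 7.6, 8.7, 9.5, 10.9, 12.2, 14.3, 16.3, 18.3, 20.5,
             23.0, 25.8, 28.7, 32.0, 36.0, 40.5, 45.5, 50.5, 55.0, 58.0,
             60.0, 61.5, 63.0),
  height = c(0.545, 0.600, 0.660, 0.705, 0.750, 0.815, 0.870, 0.960, 1.030,
             1.100, 1.160, 1.220, 1.280, 1.335, 1.385, 1.440, 1.500, 1.565,
             1.625, 1.670, 1.700, 1.715, 1.725, 1.730)
)

.creat_ref <- data.frame(
  age = c(0.1, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 19.3),
  creat = c(18, 20, 22, 26, 31, 35, 39, 43, 47, 51, 54, 56)  # umol/L
)

ref_median <- function(age, ref, col) {
  stats::approx(ref$age, ref[[col]], xout = age, rule = 2)$y
}

#' Virtual-cohort specification
#'
#' Settings of the synthetic pediatric cohort generator: how many virtual
#' patients per age stratum, the age ranges, and the variability of the
#' anthropometry and creatinine models around their age-reference medians.
#'
#' @param n_per_group Number of virtual patients in each of the three age
#'   strata (`<2`, `2-12`, `>12` years).
#' @param age_ranges List of length-2 numeric vectors giving the sampled age
#'   range of each stratum.
#' @param cv_weight,cv_height,cv_creat Coefficients of variation of the
#'   lognormal inter-child variability around the reference medians.
#' @param creat_band Multiplicative truncation band around the creatinine
#'   age-median, keeping generated values "age-related normal".
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 1000,
                        age_ranges = list("<2" = c(0.1, 2),
                                          "2-12" = c(2, 12),
                                          ">12" = c(12, 19.3)),
                        cv_weight = 0.12, cv_height = 0.04, cv_creat = 0.15,
                        creat_band = c(0.6, 1.6)) {
  if (any(n_per_group < 0)) stop("cohort_spec: n_per_group must be >= 0", call. = FALSE)
  structure(list(n_per_group = n_per_group, age_ranges = age_ranges,
                 cv_weight = cv_weight, cv_height = cv_height,
                 cv_creat = cv_creat, creat_band = creat_band),
            class = "cohort_spec")
}

#' Generate a virtual pediatric cohort
#'
#' Draws synthetic covariate records emulating a pediatric CF population with
#' age-related normal serum creatinine: age uniform within each stratum,
#' height and weight lognormally dispersed around growth-reference medians
#' (weight partially tracking height), and creatinine lognormally dispersed
#' around an age-dependent normal median, truncated to the normal band.
#' Gestational age is fixed at 40 weeks (term) for all virtual patients.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return A `patient_covariates` data.frame with an additional `group`
#'   column (age stratum) and `id`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 5), seed = 1)
#' coh[, c("id", "group", "age", "weight", "height", "creatinine_umol_l")]
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- names(spec$age_ranges)
  n <- rep_len(spec$n_per_group, length(groups))
  if (sum(n) == 0) {
    out <- patient_covariates(age = numeric(0), weight = numeric(0),
                              height = numeric(0), creatinine = numeric(0),
                              creatinine_unit = character(0))
    out$group <- factor(character(0), levels = groups)
    out$id <- integer(0)
    return(out)
  }
  sd_h <- sqrt(log(1 + spec$cv_height^2))
  sd_w_total <- sqrt(log(1 + spec$cv_weight^2))
  # weight scales ~ height^2 for a given age; residual spread on top of that
  sd_w_resid <- sqrt(max(sd_w_total^2 - (2 * sd_h)^2, 0.002))
  sd_c <- sqrt(log(1 + spec$cv_creat^2))

  rows <- lapply(seq_along(groups), function(g) {
    if (n[g] == 0) return(NULL)
    rng <- spec$age_ranges[[g]]
    age <- stats::runif(n[g], rng[1], rng[2])
    eps_h <- stats::rnorm(n[g], 0, sd_h)
    height <- ref_median(age, .growth_ref, "height") * exp(eps_h)
    weight <- ref_median(age, .growth_ref, "weight") *
      exp(2 * eps_h + stats::rnorm(n[g], 0, sd_w_resid))
    med_c <- ref_median(age, .creat_ref, "creat")
    creat <- med_c * exp(stats::rnorm(n[g], 0, sd_c))
    creat <- pmin(pmax(creat, spec$creat_band[1] * med_c),
                  spec$creat_band[2] * med_c)
    data.frame(group = groups[g], age = age, weight = weight, height = height,
               creat = creat)
  })
  d <- do.call(rbind, rows)
  out <- patient_covariates(age = d$age, weight = d$weight, height = d$height,
                            creatinine = d$creat, creatinine_unit = "umol/L",
                            gestational_age = 40)
  out$group <- factor(d$group, levels = groups)
  out$id <- seq_len(nrow(out))
  out
}
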