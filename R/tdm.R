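#' Therapeutic drug monitoring sampling design
#'
#' Sampling windows relative to the start of each monitored infusion,
#' following once-daily TDM practice: one early sample 1-2 h and one late
#' sample 4-8 h after the start of the infusion.
#'
#' @param windows List of length-2 numeric vectors (h after infusion start);
#'   one sample is drawn uniformly within each window per monitored dose.
#' @param occasions Which dose numbers are monitored (1 = first dose).
#' @param lloq Lower limit of quantification (mg/L).
#' @param n_doses Total number of once-daily doses administered.
#' @return An object of class `tdm_design`.
#' @export
tdm_design <- function(windows = list(c(1, 2), c(4, 8)),
                       occasions = c(1, 3, 5), lloq = 0.6, n_doses = 7) {
  if (lloq <= 0) stop("tdm_design: lloq must be positive", call. = FALSE)
  for (w in windows) {
    if (length(w) != 2L || w[1] > w[2] || w[1] < 0 || w[2] > 24) {
      stop("tdm_design: each window must lie within the 24 h dosing interval",
           call. = FALSE)
    }
  }
  if (any(occasions < 1) || any(occasions > n_doses)) {
    stop("tdm_design: occasions must reference administered doses", call. = FALSE)
  }
  structure(list(windows = windows, occasions = occasions, lloq = lloq,
                 n_doses = n_doses), class = "tdm_design")
}

#' Flag below-quantification observations
#'
#' Marks observation records whose concentration is strictly below the lower
#' limit of quantification and withholds their value. A concentration exactly
#' at the limit is quantifiable and not flagged.
#'
#' @param records A data.frame with a `DV` column (and optionally `EVID`;
#'   only observation rows, `EVID == 0`, are considered).
#' @param lloq Lower limit of quantification (mg/L), positive.
#' @return The records with a logical `BLQ` column set and `DV` of censored
#'   rows replaced by `NA`.
#' @examples
#' censor_blq(data.frame(DV = c(0.59, 0.60, 2.1)), lloq = 0.6)$BLQ
#' @export
censor_blq <- function(records, lloq = 0.6) {
  if (lloq <= 0) stop("censor_blq: lloq must be positive", call. = FALSE)
  if (nrow(records) == 0) {
    records$BLQ <- logical(0)
    return(records)
  }
  obs <- if (!is.null(records$EVID)) records$EVID == 0 else rep(TRUE, nrow(records))
  blq <- obs & !is.na(records$DV) & records$DV < lloq
  records$BLQ <- blq
  records$DV[blq] <- NA_real_
  records
}

#' Simulate a synthetic TDM dataset
#'
#' Generates longitudinal dosing/concentration records from the full model:
#' per patient, draw lognormal random effects on clearance, volume and
#' infusion duration, administer once-daily infusions dosed per the regimen
#' policy, sample concentrations in the TDM windows of the monitored doses,
#' add combined additive + proportional residual error
#' (`y = f * (1 + eps_prop) + eps_add`), and censor observations below the
#' quantification limit. Records follow the NONMEM-style event convention
#' (dose rows `EVID = 1` with `AMT`/`DUR`, observation rows `EVID = 0` with
#' `DV`/`MDV`).
#'
#' @param cohort A `patient_covariates` data.frame (e.g. from
#'   [generate_cohort()]).
#' @param design A [tdm_design()].
#' @param pop A [pop_params()] object; `theta_D1` is the typical infusion
#'   duration of the data-generating model.
#' @param policy A [dosing_policy()]; daily dose is `standard_perkg * weight`.
#' @param seed Optional integer seed.
#' @return A data.frame of class `pk_dataset` with columns `ID`, `TIME`,
#'   `EVID`, `AMT`, `DUR`, `DV`, `MDV`, `BLQ`, `INTERVAL`, covariates
#'   (`AGE`, `WT`, `HT`, `SCR`, `SCRU`, `GA`), and attributes `etas` (the
#'   generating random effects) and `lloq`.
#' @export
simulate_tdm <- function(cohort, design = tdm_design(), pop = pop_params(),
                         policy = dosing_policy(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(cohort) == 0) stop("simulate_tdm: empty cohort", call. = FALSE)
  if (is.null(cohort$id)) cohort$id <- seq_len(nrow(cohort))
  tcl <- typical_cl(cohort, pop)
  tv <- typical_v(cohort, pop)
  n <- nrow(cohort)
  eta <- data.frame(
    id = cohort$id,
    eta_CL = stats::rnorm(n, 0, pop$omega_CL),
    eta_V = stats::rnorm(n, 0, pop$omega_V),
    eta_D1 = stats::rnorm(n, 0, pop$omega_D1)
  )
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dose <- policy$standard_perkg * cohort$weight[i]
    CL <- tcl[i] * exp(eta$eta_CL[i])
    V <- tv[i] * exp(eta$eta_V[i])
    D1 <- pop$theta_D1 * exp(eta$eta_D1[i])
    reg <- dose_regimen(dose, tau = 24, infusion_duration = min(D1, 24),
                        n_doses = design$n_doses)
    dose_rows <- data.frame(
      ID = cohort$id[i], TIME = (seq_len(design$n_doses) - 1) * 24,
      EVID = 1L, AMT = dose, DUR = 0.5, DV = NA_real_, MDV = 1L
    )
    offs <- unlist(lapply(design$windows,
                          function(w) stats::runif(1, w[1], w[2])))
    tobs <- sort(as.vector(outer((design$occasions - 1) * 24, offs, `+`)))
    f <- pk_concentration(list(CL = CL, V = V, D1 = min(D1, 24)), reg, tobs)
    y <- f * (1 + stats::rnorm(length(f), 0, pop$sigma_prop)) +
      stats::rnorm(length(f), 0, pop$sigma_add)
    y <- pmax(y, 0)
    obs_rows <- data.frame(ID = cohort$id[i], TIME = tobs, EVID = 0L,
                           AMT = NA_real_, DUR = NA_real_, DV = y, MDV = 0L)
    sub <- rbind(dose_rows, obs_rows)
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    sub$AGE <- cohort$age[i]; sub$WT <- cohort$weight[i]
    sub$HT <- cohort$height[i]; sub$SCR <- cohort$creatinine_umol_l[i]
    sub$SCRU <- "umol/L"; sub$GA <- cohort$gestational_age[i]
    rows[[i]] <- sub
  }
  d <- do.call(rbind, rows)
  d$INTERVAL <- floor(d$TIME / 24) + 1L
  d <- censor_blq(d, design$lloq)
  rownames(d) <- NULL
  class(d) <- c("pk_dataset", "data.frame")
  attr(d, "etas") <- eta
  attr(d, "lloq") <- design$lloq
  d
}
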