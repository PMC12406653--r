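#' Read and write longitudinal PK datasets
#'
#' CSV serialization of the NONMEM-style event layout used throughout the
#' package: one row per dose (`EVID = 1`, `AMT` mg, `DUR` h) or observation
#' (`EVID = 0`, `DV` mg/L, `MDV`, `BLQ`), with per-row covariates `AGE`
#' (years), `WT` (kg), `HT` (m), `SCR` + `SCRU` (serum creatinine and its
#' unit; the unit column is mandatory) and `GA` (weeks). Validation reports
#' the offending rows/columns by name.
#'
#' @param path File path.
#' @param dataset A `pk_dataset` data.frame.
#' @return `read_pk_dataset()` returns a validated `pk_dataset`;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_pk_dataset(d)
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(dataset, path) {
  validate_pk_dataset(as.data.frame(dataset))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

validate_pk_dataset <- function(d) {
  req <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("pk dataset: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if ("SCR" %in% names(d) && !"SCRU" %in% names(d)) {
    stop("pk dataset: creatinine column SCR present without its unit column SCRU; ",
         "units must be declared", call. = FALSE)
  }
  if (any(d$TIME < 0)) {
    stop("pk dataset: negative TIME in row(s) ",
         paste(utils::head(which(d$TIME < 0), 5), collapse = ", "), call. = FALSE)
  }
  for (id in unique(d$ID)) {
    sub <- d[d$ID == id, ]
    if (is.unsorted(sub$TIME)) {
      stop("pk dataset: times not non-decreasing within subject ", id,
           call. = FALSE)
    }
    obs_t <- sub$TIME[sub$EVID == 0]
    if (length(obs_t)) {
      first_dose <- suppressWarnings(min(sub$TIME[sub$EVID == 1]))
      if (!is.finite(first_dose) || any(obs_t < first_dose)) {
        stop("pk dataset: subject ", id,
             " has observation(s) before any dose record", call. = FALSE)
      }
    }
  }
  if (is.null(d$BLQ)) d$BLQ <- FALSE
  d$BLQ <- as.logical(d$BLQ) & !is.na(d$BLQ)
  if (is.null(d$INTERVAL) && "TIME" %in% names(d)) {
    d$INTERVAL <- floor(d$TIME / 24) + 1L
  }
  class(d) <- c("pk_dataset", "data.frame")
  d
}

#' Read and write virtual cohorts
#'
#' Cohort tables are CSV with unit-bearing headers (`age_yr`, `weight_kg`,
#' `height_m`, `creatinine_umol_l`, `gestational_age_wk`).
#'
#' @param cohort A `patient_covariates` data.frame (with optional `group`,
#'   `id` columns).
#' @param path File path.
#' @return `read_cohort()` returns a `patient_covariates` data.frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(id = cohort$id %||% seq_len(nrow(cohort)),
                    group = cohort$group %||% age_group(cohort$age),
                    age_yr = cohort$age, weight_kg = cohort$weight,
                    height_m = cohort$height,
                    creatinine_umol_l = cohort$creatinine_umol_l,
                    gestational_age_wk = cohort$gestational_age,
                    sex = cohort$sex %||% NA_character_)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("age_yr", "weight_kg", "height_m", "creatinine_umol_l")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("cohort: missing column(s): ", paste(missing_cols, collapse = ", "),
         " (unit-bearing headers are required)", call. = FALSE)
  }
  out <- patient_covariates(age = d$age_yr, weight = d$weight_kg,
                            height = d$height_m,
                            creatinine = d$creatinine_umol_l,
                            creatinine_unit = "umol/L",
                            gestational_age = d$gestational_age_wk %||% 40,
                            sex = d$sex %||% NA_character_)
  out$group <- if (!is.null(d$group)) {
    factor(d$group, levels = levels(age_group(0)))
  } else age_group(out$age)
  out$id <- d$id %||% seq_len(nrow(out))
  out
}

#' Run configuration
#'
#' A single configuration object holding every model and simulation constant
#' (population parameters, dosing policy, simulation and cohort settings,
#' TDM design, global seed), round-trippable through YAML or JSON so that a
#' run is fully reproducible from `(config, seed)`.
#'
#' @param pop,policy,sim,cohort,tdm Component settings; defaults are the
#'   package defaults.
#' @param seed Global seed, expanded into per-stage substreams via
#'   [substream_seed()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(pop = pop_params(), policy = dosing_policy(),
                       sim = sim_config(), cohort = cohort_spec(),
                       tdm = tdm_design(), seed = 20251001) {
  structure(list(pop = unclass(pop), policy = unclass(policy),
                 sim = unclass(sim), cohort = unclass(cohort),
                 tdm = unclass(tdm), seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # JSON simplification can collapse the list of sampling windows to a matrix
  if (is.matrix(x$tdm$windows)) {
    x$tdm$windows <- lapply(seq_len(nrow(x$tdm$windows)),
                            function(i) as.numeric(x$tdm$windows[i, ]))
  }
  x$cohort$age_ranges <- lapply(x$cohort$age_ranges, as.numeric)
  cfg <- run_config(
    pop = do.call(pop_params, x$pop),
    policy = do.call(dosing_policy, x$policy[c("target_auc", "cap_abs",
                                               "cap_perkg", "standard_perkg",
                                               "window_low", "window_high")]),
    sim = do.call(sim_config, x$sim),
    cohort = do.call(cohort_spec, x$cohort),
    tdm = do.call(tdm_design, x$tdm),
    seed = x$seed
  )
  cfg
}

#' Short reproducibility hash of a configuration
#'
#' @param config Any serializable object.
#' @return An 8-hex-digit string, deterministic in the configuration content.
#' @export
config_hash <- function(config) {
  # JSON canonicalization makes the hash insensitive to integer/double storage
  s <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     digits = 10, force = TRUE))
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
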