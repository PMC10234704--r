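# Seeded synthetic case-control cohort generator.
#
# Emulates a two-arm emergency-department case-control cohort for acute
# aortic syndrome: each clinical feature is drawn independently per record
# as a Bernoulli with the arm-specific prevalence from the published cohort
# characteristics, and the three-level clinical impression is drawn
# categorically. Only marginal prevalences are published, so features are
# independent within arm by default.

#' Default per-arm feature prevalences
#'
#' Case/control prevalences of each boolean clinical feature, taken from the
#' published cohort-characteristics table (379 patients per arm). The
#' thoracic-aneurysm probability is a marginal: the generator draws the
#' thoracic flag only among records with a known aortic aneurysm, at the
#' implied conditional rate.
#'
#' @return A tibble with columns `feature`, `case`, `control`.
#' @export
default_prevalences <- function() {
  tibble::tribble(
    ~feature,                         ~case,  ~control,
    "family_history",                 0.015,  0.002,
    "aortic_manipulation",            0.003,  0.000,
    "aortic_valve_disease",           0.037,  0.000,
    "connective_tissue_disease",      0.002,  0.000,
    "known_aortic_aneurysm",          0.182,  0.005,
    "known_thoracic_aortic_aneurysm", 0.060,  0.000,
    "abrupt_onset_pain",              0.812,  0.132,
    "tearing_ripping",                0.058,  0.0026,
    "migrating_radiating",            0.797,  0.164,
    "severe_pain",                    0.246,  0.239,
    "hypotension",                    0.139,  0.003,
    "new_murmur",                     0.042,  0.000,
    "pulse_deficit",                  0.053,  0.003,
    "focal_neuro_deficit",            0.108,  0.000,
    "bp_differential_gt20",           0.076,  0.005,
    "cxr_abnormal",                   0.131,  0.000
  )
}

#' Generator configuration
#'
#' Defines the synthetic cohort's stated world: arm sizes (default 379/379,
#' the published study population), per-arm Bernoulli feature prevalences,
#' the per-arm distribution of the three-level clinical impression, and the
#' demographic margins (mean age 68.5 y, 52.3% female).
#'
#' The published table fixes only the probability of an
#' `alternative_likely` impression (0.106 in cases, 0.298 in controls); the
#' remaining mass is split between `unsure` and `aas_most_likely` by
#' `impression_split` (proportion given to `unsure`), defaulting to 20/80 in
#' cases and 50/50 in controls — uncalibrated, configurable.
#'
#' @param n_cases,n_controls Arm sizes (positive integers).
#' @param prevalences Tibble like [default_prevalences()].
#' @param p_alternative Named numeric: per-arm probability of the
#'   `alternative_likely` impression level.
#' @param impression_split Named numeric: per-arm share of the non-alternative
#'   mass assigned to `unsure` (the rest goes to `aas_most_likely`).
#' @param age_mean,age_sd Normal age model, truncated at 18 years.
#' @param female_fraction Probability a record is female.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_cases = 379L,
                             n_controls = 379L,
                             prevalences = default_prevalences(),
                             p_alternative = c(case = 0.106, control = 0.298),
                             impression_split = c(case = 0.2, control = 0.5),
                             age_mean = 68.5,
                             age_sd = 15,
                             female_fraction = 0.523,
                             seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              prevalences = tibble::as_tibble(prevalences),
              p_alternative = p_alternative, impression_split = impression_split,
              age_mean = age_mean, age_sd = age_sd,
              female_fraction = female_fraction, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_cases <= 0L || cfg$n_controls <= 0L) {
    stop("config error: arm sizes must be positive", call. = FALSE)
  }
  pr <- cfg$prevalences
  need <- c("feature", "case", "control")
  if (!all(need %in% names(pr))) {
    stop("config error: prevalence table needs columns feature, case, control",
         call. = FALSE)
  }
  probs <- c(pr$case, pr$control, cfg$p_alternative, cfg$impression_split,
             cfg$female_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("config error: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(pr$feature, boolean_fields())
  if (length(bad)) {
    stop(sprintf("config error: unknown feature(s) in prevalence table: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(cfg)
}

impression_probs <- function(cfg, arm) {
  p_alt <- cfg$p_alternative[[arm]]
  split <- cfg$impression_split[[arm]]
  c(alternative_likely = p_alt,
    unsure = (1 - p_alt) * split,
    aas_most_likely = (1 - p_alt) * (1 - split))
}

generate_arm <- function(cfg, arm, n) {
  pr <- cfg$prevalences
  out <- tibble::tibble(
    id = sprintf("%s_%04d", arm, seq_len(n)),
    arm = factor(arm, levels = arm_levels()),
    age = pmax(18, stats::rnorm(n, cfg$age_mean, cfg$age_sd)),
    sex = factor(ifelse(stats::runif(n) < cfg$female_fraction, "female", "male"),
                 levels = sex_levels())
  )
  for (i in seq_len(nrow(pr))) {
    feature <- pr$feature[[i]]
    if (feature == "known_thoracic_aortic_aneurysm") next
    out[[feature]] <- stats::runif(n) < pr[[arm]][[i]]
  }
  # Thoracic aneurysm is a subtype: drawn only among known-aneurysm records,
  # at the conditional rate implied by the two marginals.
  p_an <- pr[[arm]][pr$feature == "known_aortic_aneurysm"]
  p_th <- pr[[arm]][pr$feature == "known_thoracic_aortic_aneurysm"]
  p_cond <- if (p_an > 0) min(1, p_th / p_an) else 0
  out$known_thoracic_aortic_aneurysm <-
    out$known_aortic_aneurysm & (stats::runif(n) < p_cond)
  probs <- impression_probs(cfg, arm)
  out$impression <- factor(
    sample(impression_levels(), n, replace = TRUE, prob = probs),
    levels = impression_levels()
  )
  # Eligibility fields: generated records are eligible by construction.
  out$pain_duration_days <- pmin(stats::rexp(n, rate = 1), 14)
  out$recent_trauma_24h <- FALSE
  out[, names(patient_fields())]
}

#' Generate a synthetic case-control cohort
#'
#' Draws `n_cases + n_controls` records per [generator_config()]: each boolean
#' feature independently Bernoulli with its arm prevalence, impression
#' categorical over the three levels, the thoracic-aneurysm flag only among
#' known-aneurysm records. Deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A cohort tibble of `n_cases + n_controls` fully-resolved records.
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  records <- with_local_seed(config$seed, {
    rbind(generate_arm(config, "case", config$n_cases),
          generate_arm(config, "control", config$n_controls))
  })
  new_cohort(records, provenance = "synthetic", seed = config$seed)
}

#' Observed per-arm feature prevalences
#'
#' The calibration check for the generator: the observed proportion of each
#' boolean feature per arm, plus the observed probability of each impression
#' level (rows `impression_<level>`).
#'
#' @param cohort A cohort tibble with non-empty arms.
#' @return A tibble with columns `feature`, `case`, `control`.
#' @export
estimate_prevalences <- function(cohort) {
  sizes <- arm_sizes(cohort)
  if (any(sizes == 0)) {
    stop("cannot estimate prevalences: empty arm(s): ",
         paste(names(sizes)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  prop <- function(x, arm) mean(x[cohort$arm == arm], na.rm = TRUE)
  feats <- setdiff(boolean_fields(), "recent_trauma_24h")
  rows <- lapply(feats, function(f) {
    tibble::tibble(feature = f,
                   case = prop(cohort[[f]], "case"),
                   control = prop(cohort[[f]], "control"))
  })
  imp_rows <- lapply(impression_levels(), function(lv) {
    tibble::tibble(feature = paste0("impression_", lv),
                   case = prop(cohort$impression == lv, "case"),
                   control = prop(cohort$impression == lv, "control"))
  })
  do.call(rbind, c(rows, imp_rows))
}
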