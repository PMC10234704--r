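# Programmatic fixtures: patient records with sensible defaults, overridable
# per field, and a random-record generator for property-style tests.

record <- function(...) {
  defaults <- list(
    id = NA_character_, arm = "case", age = 50, sex = "female",
    family_history = FALSE, aortic_manipulation = FALSE,
    aortic_valve_disease = FALSE, connective_tissue_disease = FALSE,
    known_aortic_aneurysm = FALSE, known_thoracic_aortic_aneurysm = FALSE,
    abrupt_onset_pain = FALSE, tearing_ripping = FALSE,
    migrating_radiating = FALSE, severe_pain = FALSE,
    hypotension = FALSE, new_murmur = FALSE, pulse_deficit = FALSE,
    focal_neuro_deficit = FALSE, bp_differential_gt20 = FALSE,
    impression = "unsure", cxr_abnormal = FALSE,
    pain_duration_days = 1, recent_trauma_24h = FALSE
  )
  overrides <- list(...)
  stopifnot(all(names(overrides) %in% names(defaults)))
  defaults[names(overrides)] <- overrides
  tibble::as_tibble(defaults)
}

bind_records <- function(...) {
  out <- do.call(rbind, list(...))
  out$id <- ifelse(is.na(out$id), sprintf("r%03d", seq_len(nrow(out))), out$id)
  out$arm <- factor(out$arm, levels = c("case", "control"))
  out$sex <- factor(out$sex, levels = c("female", "male", "other"))
  out$impression <- factor(out$impression,
                           levels = c("alternative_likely", "unsure", "aas_most_likely"))
  out
}

random_records <- function(n, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bools <- setdiff(boolean_fields(), "recent_trauma_24h")
  out <- tibble::tibble(
    id = sprintf("x%05d", seq_len(n)),
    arm = factor(sample(c("case", "control"), n, replace = TRUE),
                 levels = c("case", "control")),
    age = runif(n, 18, 95),
    sex = factor(sample(c("female", "male"), n, replace = TRUE),
                 levels = c("female", "male", "other"))
  )
  for (f in bools) out[[f]] <- runif(n) < p
  out$recent_trauma_24h <- FALSE
  out$impression <- factor(
    sample(c("alternative_likely", "unsure", "aas_most_likely"), n, replace = TRUE),
    levels = c("alternative_likely", "unsure", "aas_most_likely"))
  out$pain_duration_days <- runif(n, 0, 10)
  out[, names(patient_fields())]
}
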