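# Patient-record data model and cohort ingestion/eligibility machinery.
#
# A cohort is a tibble with one emergency-department presentation per row:
# boolean clinical features, a three-level clinical impression, and a
# case/control arm label giving the reference-standard AAS status.

#' Patient record schema
#'
#' Field names and types of the patient-record data model. Boolean clinical
#' features follow the published cohort-characteristics table (risk factors,
#' pain descriptors, physical-exam findings, chest X-ray); `impression` is the
#' three-level chart-derived clinical suspicion variable; `pain_duration_days`
#' and `recent_trauma_24h` exist only for eligibility screening.
#'
#' @return A named character vector mapping field name to type
#'   (`"character"`, `"numeric"`, `"logical"`, `"factor"`).
#' @export
patient_fields <- function() {
  c(
    id = "character",
    arm = "factor",
    age = "numeric",
    sex = "factor",
    family_history = "logical",
    aortic_manipulation = "logical",
    aortic_valve_disease = "logical",
    connective_tissue_disease = "logical",
    known_aortic_aneurysm = "logical",
    known_thoracic_aortic_aneurysm = "logical",
    abrupt_onset_pain = "logical",
    tearing_ripping = "logical",
    migrating_radiating = "logical",
    severe_pain = "logical",
    hypotension = "logical",
    new_murmur = "logical",
    pulse_deficit = "logical",
    focal_neuro_deficit = "logical",
    bp_differential_gt20 = "logical",
    impression = "factor",
    cxr_abnormal = "logical",
    pain_duration_days = "numeric",
    recent_trauma_24h = "logical"
  )
}

#' @rdname patient_fields
#' @export
boolean_fields <- function() {
  names(patient_fields())[patient_fields() == "logical"]
}

arm_levels <- function() c("case", "control")
sex_levels <- function() c("female", "male", "other")
impression_levels <- function() c("alternative_likely", "unsure", "aas_most_likely")

parse_boolean <- function(x, field, strict = TRUE) {
  if (is.logical(x)) return(x)
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(tok))
  out[tok %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[tok %in% c("0", "false", "no", "f", "n")] <- FALSE
  bad <- !is.na(tok) & tok != "" & tok != "na" & is.na(out)
  if (any(bad) && strict) {
    stop(sprintf("unparseable boolean value(s) %s in column '%s' (rows %s)",
                 paste(unique(tok[bad]), collapse = ", "), field,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  as.logical(out)
}

new_cohort <- function(records, provenance = "unspecified", seed = NA_integer_) {
  records <- tibble::as_tibble(records)
  if (anyDuplicated(records$id)) {
    stop("cohort ids must be unique", call. = FALSE)
  }
  structure(records,
            provenance = provenance, seed = seed,
            class = c("aas_cohort", class(records)))
}

#' Read a cohort from CSV
#'
#' Reads a patient-level cohort. The header must contain `id` and `arm`
#' columns; `arm` values must parse as `case`/`control`. Boolean columns
#' accept `1/0`, `true/false`, `yes/no` (case-insensitive); empty cells become
#' missing and are resolved downstream by [apply_missing_policy()]. Unknown
#' columns are dropped with a warning; with `schema_strict = TRUE`, all schema
#' columns must be present.
#'
#' @param path Path to a UTF-8, comma-separated CSV file with a header.
#' @param schema_strict Require every schema column (default `TRUE`). When
#'   `FALSE`, absent columns are created as missing.
#' @return A cohort tibble (`aas_cohort`).
#' @export
read_cohort <- function(path, schema_strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("cohort file '%s' does not exist", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  fields <- patient_fields()
  for (col in c("id", "arm")) {
    if (!col %in% names(raw)) {
      stop(sprintf("schema error: required column '%s' missing from '%s'", col, path),
           call. = FALSE)
    }
  }
  unknown <- setdiff(names(raw), c(names(fields), "eligible"))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown column(s): %s", paste(unknown, collapse = ", ")),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  missing_cols <- setdiff(names(fields), names(raw))
  if (length(missing_cols) && schema_strict) {
    stop(sprintf("schema error: missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(raw)
  out <- tibble::tibble(.rows = n)
  for (field in names(fields)) {
    x <- if (field %in% names(raw)) raw[[field]] else rep(NA_character_, n)
    x[!is.na(x) & trimws(x) == ""] <- NA_character_
    out[[field]] <- switch(
      fields[[field]],
      character = as.character(x),
      numeric = as.numeric(x),
      logical = parse_boolean(x, field),
      factor = x
    )
  }
  arm_tok <- tolower(trimws(out$arm))
  bad_arm <- which(is.na(arm_tok) | !arm_tok %in% arm_levels())
  if (length(bad_arm)) {
    stop(sprintf("row error: unparseable arm value(s) '%s' at row(s) %s",
                 paste(unique(out$arm[bad_arm]), collapse = ", "),
                 paste(bad_arm, collapse = ", ")), call. = FALSE)
  }
  out$arm <- factor(arm_tok, levels = arm_levels())
  out$sex <- factor(tolower(trimws(out$sex)), levels = sex_levels())
  imp <- tolower(trimws(out$impression))
  bad_imp <- which(!is.na(imp) & !imp %in% impression_levels())
  if (length(bad_imp)) {
    stop(sprintf("row error: impression value(s) '%s' at row(s) %s not one of {%s}",
                 paste(unique(imp[bad_imp]), collapse = ", "),
                 paste(bad_imp, collapse = ", "),
                 paste(impression_levels(), collapse = ", ")), call. = FALSE)
  }
  out$impression <- factor(imp, levels = impression_levels())
  if ("eligible" %in% names(raw)) {
    out$eligible <- parse_boolean(raw$eligible, "eligible")
  }
  new_cohort(out, provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writing then reading yields a field-identical
#' cohort. Booleans are serialised as `true`/`false`; missing cells are empty.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (field in names(out)) {
    if (is.logical(out[[field]])) {
      out[[field]] <- ifelse(is.na(out[[field]]), "",
                             ifelse(out[[field]], "true", "false"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve missing values (chart-review default-to-negative policy)
#'
#' Applies the conservative chart-review convention: every missing boolean
#' feature becomes `FALSE` (absent), and a missing clinical impression becomes
#' `unsure` — the neutral zero-point level, the three-level analogue of
#' defaulting a boolean to negative. Per-field imputation counts are attached
#' as the `imputation_log` attribute and reported via `message()`.
#'
#' Idempotent: applying it twice changes nothing.
#'
#' @param cohort A cohort tibble.
#' @param quiet Suppress the imputation-count message.
#' @return The cohort with all booleans and `impression` definite.
#' @export
apply_missing_policy <- function(cohort, quiet = FALSE) {
  counts <- integer(0)
  for (field in intersect(boolean_fields(), names(cohort))) {
    n_missing <- sum(is.na(cohort[[field]]))
    if (n_missing > 0) {
      cohort[[field]][is.na(cohort[[field]])] <- FALSE
      counts[[field]] <- n_missing
    }
  }
  n_imp <- sum(is.na(cohort$impression))
  if (n_imp > 0) {
    cohort$impression[is.na(cohort$impression)] <- "unsure"
    counts[["impression"]] <- n_imp
  }
  if (!quiet && length(counts)) {
    message("imputed missing values (defaulted to negative/unsure): ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  attr(cohort, "imputation_log") <- counts
  cohort
}

exclusion_rules <- function() {
  # Printed order; a record failing several rules is tallied under the first.
  list(
    under_18 = function(df) !is.na(df$age) & df$age < 18,
    pain_duration_gt_14d = function(df) !is.na(df$pain_duration_days) & df$pain_duration_days > 14,
    trauma_within_24h = function(df) !is.na(df$recent_trauma_24h) & df$recent_trauma_24h,
    chart_ineligible = function(df) {
      if ("eligible" %in% names(df)) !is.na(df$eligible) & !df$eligible else rep(FALSE, nrow(df))
    }
  )
}

#' Apply eligibility exclusions
#'
#' Removes records that are under 18 years old, have pain duration strictly
#' greater than 14 days, or had trauma within 24 hours of pain onset. Chart
#' judgments that cannot be derived from the modelled fields (no documented
#' qualifying pain/perfusion deficit; clear alternative diagnosis at initial
#' assessment) are honoured through an optional pre-computed `eligible`
#' column. A record failing several rules is tallied once, under the first
#' matching rule in the order above.
#'
#' @param cohort A cohort tibble with eligibility fields populated.
#' @return A list with `cohort` (retained records) and `tally` (named integer
#'   vector of exclusion counts per rule, in rule order).
#' @export
apply_exclusions <- function(cohort) {
  rules <- exclusion_rules()
  tally <- stats::setNames(integer(length(rules)), names(rules))
  excluded <- rep(FALSE, nrow(cohort))
  for (rule in names(rules)) {
    hit <- rules[[rule]](cohort) & !excluded
    tally[[rule]] <- sum(hit)
    excluded <- excluded | hit
  }
  list(cohort = cohort[!excluded, , drop = FALSE], tally = tally)
}

#' Random 1:1 unmatched control selection
#'
#' Keeps every case and uniformly samples `n` controls without replacement.
#' The same seed always yields the same selection, independently of the
#' caller's RNG state.
#'
#' @param cohort A cohort tibble.
#' @param n Number of controls to retain (typically the number of cases).
#' @param seed Integer seed for the sampling stream.
#' @return A cohort with all cases and `n` sampled controls, in stable order.
#' @export
select_controls <- function(cohort, n, seed) {
  is_control <- cohort$arm == "control"
  n_avail <- sum(is_control)
  if (n > n_avail) {
    stop(sprintf("requested %d controls but only %d are eligible", n, n_avail),
         call. = FALSE)
  }
  idx_controls <- which(is_control)
  keep <- with_local_seed(seed, sort(sample(idx_controls, n)))
  out <- cohort[sort(c(which(!is_control), keep)), , drop = FALSE]
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Arm sizes of a cohort
#' @param cohort A cohort tibble.
#' @return Named integer vector with `case` and `control` counts.
#' @export
arm_sizes <- function(cohort) {
  c(case = sum(cohort$arm == "case"), control = sum(cohort$arm == "control"))
}
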