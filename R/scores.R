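# Points-based clinical risk scores.
#
# The RIPP score (Risk factors, Impression, Physical exam, Pain) is
# implemented natively; the four comparator decision tools are encoded as
# declarative `score_definition` objects evaluated by a small predicate
# engine, so their item lists are auditable and editable without touching
# code.

ripp_risk_factor_fields <- function() {
  c("family_history", "aortic_manipulation", "aortic_valve_disease",
    "connective_tissue_disease")
}
ripp_aneurysm_fields <- function() {
  c("known_aortic_aneurysm", "known_thoracic_aortic_aneurysm")
}
ripp_exam_fields <- function() {
  c("hypotension", "new_murmur", "pulse_deficit", "focal_neuro_deficit",
    "bp_differential_gt20")
}
ripp_pain_fields <- function() {
  c("abrupt_onset_pain", "tearing_ripping", "migrating_radiating", "severe_pain")
}

#' Score records with the RIPP clinical decision aid
#'
#' Computes the consensus-based RIPP score for each record:
#'
#' * **Risk factor**: 2 points for any known aortic aneurysm (thoracic counts
#'   as a subtype), else 1 point for any non-aneurysmal risk factor (family
#'   history, aortic manipulation, aortic valve disease, connective tissue
#'   disease), else 0.
#' * **Impression**: alternative diagnosis likely −1, unsure 0, AAS most
#'   likely +2.
#' * **Physical exam**: 2 points if any of hypotension, new murmur, pulse
#'   deficit, focal neurological deficit, or bilateral blood-pressure
#'   differential >20 mmHg; else 0.
#' * **Pain**: number of high-risk pain features (abrupt onset,
#'   tearing/ripping, migrating/radiating, severe) banded 0 features → 0,
#'   1–2 → 1, >2 → 2.
#'
#' The total ranges over \[−1, 8\]. The published scorecard leaves a total of
#' exactly 1 between its "<1: no further investigation" and ">1: investigate"
#' bands; the default convention classifies high risk at total ≥ 1
#' (sensitivity-first), with total ≥ 2 available via `threshold = "ge2"`.
#'
#' @param records A cohort tibble (or any data frame with the scoring fields),
#'   fully resolved — run [apply_missing_policy()] first.
#' @param threshold High-risk convention: `"ge1"` (default) or `"ge2"`.
#' @return A tibble with one row per record: `id`, the four component point
#'   columns, `total`, and `high_risk`.
#' @export
score_ripp <- function(records, threshold = c("ge1", "ge2")) {
  threshold <- match.arg(threshold)
  needed <- c(ripp_risk_factor_fields(), ripp_aneurysm_fields(),
              ripp_exam_fields(), ripp_pain_fields(), "impression")
  for (field in needed) {
    if (anyNA(records[[field]])) {
      stop(sprintf("unresolved missing values in '%s': run apply_missing_policy() first",
                   field), call. = FALSE)
    }
  }
  any_of <- function(fields) {
    Reduce(`|`, lapply(fields, function(f) records[[f]]))
  }
  risk_factor_points <- ifelse(any_of(ripp_aneurysm_fields()), 2L,
                               ifelse(any_of(ripp_risk_factor_fields()), 1L, 0L))
  impression_points <- c(alternative_likely = -1L, unsure = 0L,
                         aas_most_likely = 2L)[as.character(records$impression)]
  exam_points <- ifelse(any_of(ripp_exam_fields()), 2L, 0L)
  n_pain <- Reduce(`+`, lapply(ripp_pain_fields(), function(f) as.integer(records[[f]])))
  pain_points <- ifelse(n_pain == 0L, 0L, ifelse(n_pain <= 2L, 1L, 2L))
  total <- risk_factor_points + unname(impression_points) + exam_points + pain_points
  cut <- if (threshold == "ge1") 1L else 2L
  tibble::tibble(
    id = if ("id" %in% names(records)) records$id else as.character(seq_len(nrow(records))),
    risk_factor_points = as.integer(risk_factor_points),
    impression_points = as.integer(unname(impression_points)),
    exam_points = as.integer(exam_points),
    pain_points = as.integer(pain_points),
    total = as.integer(total),
    high_risk = total >= cut
  )
}

allowed_predicate_calls <- function() c("&", "|", "!", "(", "==", "!=", "&&", "||")

validate_predicate <- function(expr, fields) {
  walk <- function(e) {
    if (is.name(e)) {
      nm <- as.character(e)
      if (!nm %in% fields) {
        stop(sprintf("definition error: predicate references unknown field '%s'", nm),
             call. = FALSE)
      }
    } else if (is.call(e)) {
      fun <- as.character(e[[1]])
      if (!fun %in% allowed_predicate_calls()) {
        stop(sprintf("definition error: operator '%s' not allowed in predicates", fun),
             call. = FALSE)
      }
      lapply(as.list(e)[-1], walk)
    } else if (!is.character(e) && !is.logical(e)) {
      stop("definition error: predicates may use only field tests, &, |, !, ==",
           call. = FALSE)
    }
    invisible(NULL)
  }
  walk(expr)
}

#' Declarative score definition
#'
#' A points-based decision-tool rule: named items, each a predicate over
#' patient-record fields (conjunction/disjunction/negation and equality tests
#' only — no arithmetic, so definitions stay auditable), with either summed
#' item points (`aggregation = "sum_points"`) or a count of categories
#' containing at least one satisfied item (`"count_categories"`), dichotomised
#' at `high_risk_threshold` with comparator `>=` or `>`.
#'
#' Predicates are validated at construction: referencing an undeclared field
#' is an error at load time, not scoring time.
#'
#' @param name Tool identifier (lower-case key).
#' @param items List of items; each a list with `name`, `predicate` (string),
#'   and `points` (sum_points) or `category` (count_categories).
#' @param aggregation `"sum_points"` or `"count_categories"`.
#' @param high_risk_threshold Integer threshold.
#' @param comparator `">="` (default) or `">"`.
#' @param label Human-readable tool name.
#' @param provisional Flag for encodings transcribed from secondary sources.
#' @return A `score_definition` object.
#' @export
score_definition <- function(name, items,
                             aggregation = c("sum_points", "count_categories"),
                             high_risk_threshold = 1L,
                             comparator = c(">=", ">"),
                             label = name, provisional = FALSE) {
  aggregation <- match.arg(aggregation)
  comparator <- match.arg(comparator)
  fields <- names(patient_fields())
  if (length(items) == 0 && high_risk_threshold > 0 && comparator == ">=") {
    # empty definition: raw is always 0, low risk whenever threshold >= 1
  }
  parsed <- lapply(items, function(item) {
    stopifnot(!is.null(item$name), !is.null(item$predicate))
    expr <- str2lang(item$predicate)
    validate_predicate(expr, fields)
    if (aggregation == "sum_points" && is.null(item$points)) {
      stop(sprintf("definition error: item '%s' lacks points", item$name), call. = FALSE)
    }
    if (aggregation == "count_categories" && is.null(item$category)) {
      stop(sprintf("definition error: item '%s' lacks a category", item$name), call. = FALSE)
    }
    list(name = item$name, expr = expr,
         points = as.numeric(item$points %||% NA_real_),
         category = item$category %||% NA_character_)
  })
  structure(list(name = name, label = label, items = parsed,
                 aggregation = aggregation,
                 high_risk_threshold = as.integer(high_risk_threshold),
                 comparator = comparator, provisional = isTRUE(provisional)),
            class = "score_definition")
}

#' Load a score definition from JSON
#'
#' Reads the declarative JSON format shipped under
#' `system.file("extdata/score_definitions", package = "rippval")` and
#' validates it via [score_definition()].
#'
#' @param path Path to a definition JSON file.
#' @return A `score_definition`.
#' @export
load_score_definition <- function(path) {
  spec <- jsonlite::read_json(path)
  score_definition(
    name = spec$name, items = spec$items,
    aggregation = spec$aggregation,
    high_risk_threshold = spec$high_risk_threshold,
    comparator = spec$comparator %||% ">=",
    label = spec$label %||% spec$name,
    provisional = isTRUE(spec$provisional)
  )
}

#' Built-in comparator tool definitions
#'
#' Loads the shipped encodings of the comparator decision tools (ADD risk
#' score, Lovy, Von Kodolitsch, AORTAs) plus an engine-encoded RIPP used as
#' an internal equivalence check against [score_ripp()]. The AORTAs and Lovy
#' encodings are provisional transcriptions and are flagged as such in their
#' JSON (`"provisional": true`); replace the JSON file to change them.
#'
#' @return Named list of `score_definition` objects.
#' @export
builtin_definitions <- function() {
  dir <- system.file("extdata", "score_definitions", package = "rippval")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  defs <- lapply(files, load_score_definition)
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Dichotomise a raw score
#'
#' Pure function of the raw score and the definition's threshold/comparator.
#' Monotone in the raw score.
#'
#' @param raw Integer raw score(s).
#' @param defn A `score_definition`.
#' @return Logical: high risk.
#' @export
dichotomize <- function(raw, defn) {
  if (defn$comparator == ">=") raw >= defn$high_risk_threshold else raw > defn$high_risk_threshold
}

#' Evaluate a score definition over records
#'
#' Applies each item predicate to every record; aggregates as summed points or
#' as the number of categories with at least one satisfied item; dichotomises
#' via [dichotomize()]. The per-item (or per-category) contribution matrix is
#' attached as the `contributions` attribute; rows sum (or count) to `raw`.
#'
#' @param defn A `score_definition`.
#' @param records Resolved cohort tibble.
#' @return Tibble with `id`, `tool`, `raw`, `high_risk`.
#' @export
evaluate_definition <- function(defn, records) {
  n <- nrow(records)
  env <- as.list(records)
  sat <- vapply(defn$items, function(item) {
    v <- eval(item$expr, envir = env, enclos = baseenv())
    if (length(v) == 1L) v <- rep(v, n)
    as.logical(v)
  }, logical(n))
  if (n == 1L) sat <- matrix(sat, nrow = 1L)
  if (length(defn$items) == 0L) sat <- matrix(FALSE, nrow = n, ncol = 0L)
  if (anyNA(sat)) {
    stop("unresolved missing values: run apply_missing_policy() first", call. = FALSE)
  }
  if (defn$aggregation == "sum_points") {
    pts <- vapply(defn$items, `[[`, 0, "points")
    contributions <- sweep(sat, 2L, if (length(pts)) pts else numeric(0), `*`)
    colnames(contributions) <- vapply(defn$items, `[[`, "", "name")
    raw <- if (ncol(contributions)) rowSums(contributions) else rep(0, n)
  } else {
    cats <- vapply(defn$items, `[[`, "", "category")
    ucats <- unique(cats)
    contributions <- vapply(ucats, function(ct) {
      cols <- which(cats == ct)
      as.numeric(rowSums(sat[, cols, drop = FALSE]) > 0)
    }, numeric(n))
    if (n == 1L) contributions <- matrix(contributions, nrow = 1L,
                                         dimnames = list(NULL, ucats))
    raw <- if (ncol(contributions)) rowSums(contributions) else rep(0, n)
  }
  out <- tibble::tibble(
    id = if ("id" %in% names(records)) records$id else as.character(seq_len(n)),
    tool = defn$name,
    raw = as.integer(round(raw)),
    high_risk = dichotomize(raw, defn)
  )
  attr(out, "contributions") <- contributions
  out
}

#' Score a cohort with a set of decision tools
#'
#' Runs each named tool over every record: `"ripp"` through the native
#' [score_ripp()], everything else through its registered definition. Output
#' order is stable (records in cohort order within tool, tools in the order
#' requested).
#'
#' @param cohort Resolved cohort tibble.
#' @param tools Character vector of tool names; default all five.
#' @param ripp_threshold RIPP dichotomisation convention, see [score_ripp()].
#' @return Long tibble: `id`, `arm`, `tool`, `raw`, `high_risk`.
#' @export
score_cohort <- function(cohort,
                         tools = c("ripp", "addrs", "lovy", "aortas", "von_kodolitsch"),
                         ripp_threshold = c("ge1", "ge2")) {
  ripp_threshold <- match.arg(ripp_threshold)
  defs <- builtin_definitions()
  registered <- c("ripp", setdiff(names(defs), "ripp_engine"))
  unknown <- setdiff(tools, registered)
  if (length(unknown)) {
    stop(sprintf("unknown tool(s): %s; registered tools: %s",
                 paste(unknown, collapse = ", "),
                 paste(registered, collapse = ", ")), call. = FALSE)
  }
  arms <- cohort$arm
  res <- lapply(tools, function(tool) {
    if (tool == "ripp") {
      r <- score_ripp(cohort, threshold = ripp_threshold)
      tibble::tibble(id = r$id, arm = arms, tool = "ripp",
                     raw = r$total, high_risk = r$high_risk)
    } else {
      r <- evaluate_definition(defs[[tool]], cohort)
      tibble::tibble(id = r$id, arm = arms, tool = tool,
                     raw = r$raw, high_risk = r$high_risk)
    }
  })
  do.call(rbind, res)
}
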