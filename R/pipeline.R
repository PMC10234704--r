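# End-to-end orchestration: cohort in (synthetic or CSV) -> missing-data
# resolution -> eligibility exclusions -> 1:1 control selection -> score all
# tools -> accuracy / AUC-comparison / reclassification tables, with one
# global seed fanned out to the generator and the control sampler via
# independent derived streams.

#' Pipeline run configuration
#'
#' Exactly one input mode: `input = "synthetic"` draws a cohort from
#' `generator` (its seed is derived from the global `seed`); `input = "csv"`
#' reads `cohort_path`.
#'
#' @param input `"synthetic"` or `"csv"`.
#' @param generator A [generator_config()] for synthetic input.
#' @param cohort_path CSV path for `input = "csv"`.
#' @param tools Tools to score; see [score_cohort()].
#' @param ripp_threshold RIPP dichotomisation convention (`"ge1"`/`"ge2"`).
#' @param ci_level Confidence level for all intervals.
#' @param seed Global integer seed, recorded in all outputs.
#' @param select_1to1 Perform random 1:1 unmatched control selection when
#'   controls outnumber cases (default `TRUE`).
#' @return A `run_config` list.
#' @export
run_config <- function(input = c("synthetic", "csv"),
                       generator = generator_config(),
                       cohort_path = NULL,
                       tools = c("ripp", "addrs", "lovy", "aortas", "von_kodolitsch"),
                       ripp_threshold = c("ge1", "ge2"),
                       ci_level = 0.95,
                       seed = 1L,
                       select_1to1 = TRUE) {
  input <- match.arg(input)
  ripp_threshold <- match.arg(ripp_threshold)
  if (input == "csv" && is.null(cohort_path)) {
    stop("config error: input = 'csv' requires cohort_path", call. = FALSE)
  }
  defs <- c("ripp", setdiff(names(builtin_definitions()), "ripp_engine"))
  unknown <- setdiff(tools, defs)
  if (length(unknown)) {
    stop(sprintf("config error: unknown tool(s): %s; registered tools: %s",
                 paste(unknown, collapse = ", "), paste(defs, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(input = input, generator = generator, cohort_path = cohort_path,
                 tools = tools, ripp_threshold = ripp_threshold,
                 ci_level = ci_level, seed = as.integer(seed),
                 select_1to1 = isTRUE(select_1to1)),
            class = "run_config")
}

cohort_summary <- function(cohort) {
  sizes <- arm_sizes(cohort)
  list(
    n_cases = unname(sizes[["case"]]),
    n_controls = unname(sizes[["control"]]),
    mean_age = mean(cohort$age, na.rm = TRUE),
    pct_female = 100 * mean(cohort$sex == "female", na.rm = TRUE),
    prevalences = estimate_prevalences(cohort)
  )
}

#' Run the full validation pipeline
#'
#' Deterministic given the config seed: the generator and the control sampler
#' use independent streams derived from it. Returns the full comparison
#' report; when `out_dir` is given, also persists the resolved cohort, the
#' per-patient scores, every report table as CSV, and the report as JSON
#' (no timestamps, so identical runs are byte-identical).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return The report: a list with `cohort_summary`, `accuracy`,
#'   `auc_comparisons`, `nri`, `exclusions` and a `provenance` block.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (config$input == "synthetic") {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, 1L)
    cohort <- generate_cohort(gen)
  } else {
    cohort <- read_cohort(config$cohort_path, schema_strict = FALSE)
  }
  cohort <- apply_missing_policy(cohort, quiet = TRUE)
  excl <- apply_exclusions(cohort)
  cohort <- excl$cohort
  sizes <- arm_sizes(cohort)
  if (config$select_1to1 && sizes[["control"]] > sizes[["case"]]) {
    cohort <- select_controls(cohort, sizes[["case"]],
                              seed = derive_seed(config$seed, 2L))
  }
  scores <- score_cohort(cohort, config$tools, ripp_threshold = config$ripp_threshold)
  baseline <- if ("ripp" %in% config$tools) "ripp" else config$tools[[1]]
  acc <- accuracy_table(scores, level = config$ci_level)
  aucs <- if (length(config$tools) > 1) {
    auc_comparison_table(scores, baseline = baseline, level = config$ci_level)
  } else NULL
  nris <- if (length(config$tools) > 1) nri_table(scores, baseline = baseline) else NULL
  report <- list(
    cohort_summary = cohort_summary(cohort),
    exclusions = as.list(excl$tally),
    accuracy = acc,
    auc_comparisons = aucs,
    nri = nris,
    provenance = list(
      package = "rippval",
      version = as.character(utils::packageVersion("rippval")),
      seed = config$seed,
      input = config$input,
      tools = config$tools,
      ripp_threshold = config$ripp_threshold,
      ci_level = config$ci_level
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort_resolved.csv"))
    utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    render_report(report, "csv", out_dir)
    render_report(report, "json", out_dir)
    writeLines(render_report(report, "text"), file.path(out_dir, "report.txt"))
  }
  report
}

#' Render a comparison report
#'
#' `format = "json"` writes `report.json` to `path` (a directory);
#' `format = "csv"` writes one CSV per table; `format = "text"` returns the
#' accuracy table as fixed-format lines with percentage cells like
#' `"99.74 (98.54-99.99)"`, plus the comparison tables.
#'
#' @param report Report list from [run_pipeline()].
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param path Output directory for `"csv"`/`"json"`.
#' @return Text lines (for `"text"`), or written file paths, invisibly.
#' @export
render_report <- function(report, format = c("text", "csv", "json"), path = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    stopifnot(!is.null(path))
    file <- file.path(path, "report.json")
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(file))
  }
  if (format == "csv") {
    stopifnot(!is.null(path))
    files <- character(0)
    tables <- list(accuracy = report$accuracy,
                   auc_comparisons = report$auc_comparisons,
                   nri = report$nri,
                   prevalences = report$cohort_summary$prevalences)
    for (nm in names(tables)) {
      if (is.null(tables[[nm]])) next
      f <- file.path(path, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    return(invisible(files))
  }
  acc <- report$accuracy
  lines <- c(
    sprintf("Cohort: %d cases / %d controls; mean age %.1f; %.1f%% female",
            report$cohort_summary$n_cases, report$cohort_summary$n_controls,
            report$cohort_summary$mean_age, report$cohort_summary$pct_female),
    "",
    sprintf("%-16s %4s %4s %4s %4s  %-22s %-22s %6s",
            "Tool", "TP", "FN", "TN", "FP", "Sensitivity", "Specificity", "AUC")
  )
  for (i in seq_len(nrow(acc))) {
    r <- acc[i, ]
    lines <- c(lines, sprintf(
      "%-16s %4d %4d %4d %4d  %-22s %-22s %6.4f",
      r$tool, r$tp, r$fn, r$tn, r$fp,
      format_pct_ci(r$sensitivity, r$sens_ci_low, r$sens_ci_high),
      format_pct_ci(r$specificity, r$spec_ci_low, r$spec_ci_high),
      r$auc))
  }
  if (!is.null(report$auc_comparisons)) {
    lines <- c(lines, "", sprintf("AUC differences (%s minus tool, DeLong):",
                                  report$auc_comparisons$baseline[[1]]))
    a <- report$auc_comparisons
    for (i in seq_len(nrow(a))) {
      lines <- c(lines, sprintf(
        "  %-16s diff %+0.4f (%+0.4f to %+0.4f), p = %.4g",
        a$tool[[i]], a$difference[[i]], a$ci_low[[i]], a$ci_high[[i]], a$p_value[[i]]))
    }
  }
  if (!is.null(report$nri)) {
    lines <- c(lines, "", sprintf("Net reclassification vs %s (candidate = tool):",
                                  report$nri$baseline[[1]]))
    nr <- report$nri
    for (i in seq_len(nrow(nr))) {
      lines <- c(lines, sprintf(
        "  %-16s event %+0.4f, non-event %+0.4f, overall %+0.4f",
        nr$candidate[[i]], nr$event_nri[[i]], nr$nonevent_nri[[i]], nr$overall_nri[[i]]))
    }
  }
  lines
}
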