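# Confusion counts, sensitivity/specificity with exact binomial confidence
# intervals, and the precision-based sample-size calculation.

#' Confusion counts for one tool on one cohort
#'
#' @param high_risk Logical classification per record.
#' @param arm Arm label per record (`case`/`control`), aligned with `high_risk`.
#' @return List of class `confusion_counts`: `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(high_risk, arm) {
  if (length(high_risk) == 0) stop("empty input", call. = FALSE)
  if (length(high_risk) != length(arm)) {
    stop("high_risk and arm must be aligned and of equal length", call. = FALSE)
  }
  is_case <- arm == "case"
  structure(list(
    tp = sum(is_case & high_risk),
    fn = sum(is_case & !high_risk),
    tn = sum(!is_case & !high_risk),
    fp = sum(!is_case & high_risk)
  ), class = "confusion_counts")
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Exact interval by inverting binomial tail probabilities, computed via beta
#' quantiles: lower bound `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#' upper bound `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). This is
#' the interval family that reproduces the published accuracy tables; a
#' Wilson score interval is available behind `method = "wilson"`.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return List of class `proportion_estimate`: `point`, `ci_low`, `ci_high`,
#'   `level`, `numerator`, `denominator`.
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95,
                               method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (trials < 1 || successes < 0 || successes > trials) {
    stop(sprintf("invalid counts: successes=%s, trials=%s", successes, trials),
         call. = FALSE)
  }
  alpha <- 1 - level
  p <- successes / trials
  if (method == "clopper-pearson") {
    lo <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, trials - successes + 1)
    hi <- if (successes == trials) 1 else stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / trials
    centre <- (p + z^2 / (2 * trials)) / denom
    half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  structure(list(point = p, ci_low = lo, ci_high = hi, level = level,
                 numerator = as.integer(successes), denominator = as.integer(trials)),
            class = "proportion_estimate")
}

#' Sensitivity and specificity with confidence intervals
#'
#' Sensitivity = TP/(TP+FN) over cases, specificity = TN/(TN+FP) over
#' controls, each with its exact Clopper-Pearson interval.
#'
#' @param counts A `confusion_counts` object (or list with tp/fn/tn/fp).
#' @param level Confidence level.
#' @param method Interval family, see [clopper_pearson_ci()].
#' @return List with `sensitivity` and `specificity`, each a
#'   `proportion_estimate`.
#' @export
sens_spec <- function(counts, level = 0.95, method = "clopper-pearson") {
  n_case <- counts$tp + counts$fn
  n_control <- counts$tn + counts$fp
  if (n_case < 1) stop("no cases scored: sensitivity denominator is empty", call. = FALSE)
  if (n_control < 1) stop("no controls scored: specificity denominator is empty", call. = FALSE)
  list(
    sensitivity = clopper_pearson_ci(counts$tp, n_case, level, method),
    specificity = clopper_pearson_ci(counts$tn, n_control, level, method)
  )
}

#' Cases required for a target confidence-interval half-width
#'
#' Smallest n at which the normal-approximation half-width
#' `z * sqrt(p (1 - p) / n)` of a `level` confidence interval for an expected
#' proportion `p` does not exceed `halfwidth` — the precision-based
#' sample-size rationale for a sensitivity estimate.
#'
#' @param expected_sensitivity Anticipated proportion, strictly in (0, 1).
#' @param ci_halfwidth Target half-width, > 0.
#' @param level Confidence level.
#' @return Integer n.
#' @export
required_cases <- function(expected_sensitivity, ci_halfwidth, level = 0.95) {
  p <- expected_sensitivity
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("expected_sensitivity must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(ci_halfwidth) || ci_halfwidth <= 0) {
    stop("ci_halfwidth must be positive", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / ci_halfwidth^2))
}

#' Published diagnostic-accuracy counts
#'
#' The printed TP/FN/TN/FP counts of the validation study's accuracy table
#' (379 cases, 379 controls per tool). These are inputs for reproducing the
#' published sensitivity/specificity percentages and confidence intervals
#' from counts; they are not produced by this package's scorers.
#'
#' @return Tibble with columns `tool`, `tp`, `fn`, `tn`, `fp`.
#' @export
published_counts <- function() {
  tibble::tribble(
    ~tool,            ~tp, ~fn, ~tn, ~fp,
    "addrs",          355L, 24L, 241L, 138L,
    "lovy",           310L, 69L, 329L,  50L,
    "aortas",         346L, 33L, 243L, 136L,
    "von_kodolitsch", 329L, 50L, 326L,  53L,
    "ripp",           378L,  1L, 201L, 178L
  )
}

#' Accuracy table for scored tools
#'
#' The per-tool accuracy rows: confusion counts, sensitivity and specificity
#' (percentages with confidence intervals), and the empirical AUC of the raw
#' ordinal score.
#'
#' @param scores Long score tibble from [score_cohort()].
#' @param level Confidence level.
#' @return Tibble with one row per tool.
#' @export
accuracy_table <- function(scores, level = 0.95) {
  tools <- unique(scores$tool)
  rows <- lapply(tools, function(tool) {
    s <- scores[scores$tool == tool, ]
    cm <- confusion(s$high_risk, s$arm)
    ss <- sens_spec(cm, level)
    auc <- empirical_auc(s$raw[s$arm == "case"], s$raw[s$arm == "control"])
    tibble::tibble(
      tool = tool, tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
      sensitivity = ss$sensitivity$point,
      sens_ci_low = ss$sensitivity$ci_low, sens_ci_high = ss$sensitivity$ci_high,
      specificity = ss$specificity$point,
      spec_ci_low = ss$specificity$ci_low, spec_ci_high = ss$specificity$ci_high,
      auc = auc$auc
    )
  })
  do.call(rbind, rows)
}

#' Format a proportion as a table cell
#'
#' Renders `point (low-high)` as percentages to two decimals with half-up
#' rounding, the published tables' style (e.g. `"99.74 (98.54-99.99)"`).
#'
#' @param est A `proportion_estimate`, or a point proportion if `ci_low` and
#'   `ci_high` are supplied.
#' @param ci_low,ci_high Optional explicit bounds (proportions).
#' @return Character cell.
#' @export
format_pct_ci <- function(est, ci_low = NULL, ci_high = NULL) {
  if (inherits(est, "proportion_estimate")) {
    p <- est$point; lo <- est$ci_low; hi <- est$ci_high
  } else {
    p <- est; lo <- ci_low; hi <- ci_high
  }
  fmt <- function(x) sprintf("%.2f", round_half_up(100 * x, 2))
  sprintf("%s (%s-%s)", fmt(p), fmt(lo), fmt(hi))
}
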