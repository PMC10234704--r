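# Empirical ROC/AUC on ordinal raw scores and the DeLong method for paired
# comparison of correlated AUCs.
#
# The AUC is the Mann-Whitney two-sample statistic (ties counted 1/2):
# the probability that a randomly chosen case scores higher than a randomly
# chosen control. Variances come from DeLong's structural components, here
# computed with midranks: for case i, V10_i is the proportion of controls it
# beats (ties 1/2); for control j, V01_j the proportion of cases beating it.

delong_components <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(cases, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(controls, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical AUC (C statistic) with DeLong variance
#'
#' `auc = (1/mn) * sum_ij [ 1(x_i > y_j) + 1/2 * 1(x_i = y_j) ]` computed via
#' midranks, with the DeLong structural-component variance
#' `var(V10)/m + var(V01)/n` attached.
#'
#' @param cases Raw scores of case records (non-empty numeric).
#' @param controls Raw scores of control records (non-empty numeric).
#' @return List of class `auc_estimate`: `auc`, `variance`, `n_cases`,
#'   `n_controls`, and the component vectors `v10`, `v01`.
#' @export
empirical_auc <- function(cases, controls) {
  if (length(cases) == 0 || length(controls) == 0) {
    stop("both score lists must be non-empty", call. = FALSE)
  }
  comp <- delong_components(cases, controls)
  variance <- if (length(cases) > 1) stats::var(comp$v10) / length(cases) else 0
  variance <- variance +
    if (length(controls) > 1) stats::var(comp$v01) / length(controls) else 0
  structure(list(auc = comp$auc, variance = variance,
                 n_cases = length(cases), n_controls = length(controls),
                 v10 = comp$v10, v01 = comp$v01),
            class = "auc_estimate")
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both tools must score the identical record set (paired design). The
#' variance of the AUC difference uses the 2x2 covariance of the structural
#' components: `(S10_aa + S10_bb - 2 S10_ab)/m + (S01_aa + S01_bb - 2 S01_ab)/n`.
#' The z statistic is `diff / sqrt(var)`, the p-value two-sided standard
#' normal, and the interval `diff +/- z_{level} * sqrt(var)` (normal
#' approximation, no continuity correction).
#'
#' A zero variance with a nonzero difference is reported as `p_value = 0`
#' with `degenerate = TRUE`; comparing a tool with itself gives difference 0,
#' variance 0, `p_value = 1`.
#'
#' @param scores_a,scores_b Raw scores of the two tools, aligned per record.
#' @param labels Arm label per record (`case`/`control`).
#' @param level Confidence level for the difference interval.
#' @return List of class `auc_comparison`: `auc_a`, `auc_b`, `difference`,
#'   `variance`, `ci_low`, `ci_high`, `z`, `p_value`, `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, level = 0.95) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("unpaired inputs: scores_a, scores_b and labels must be aligned", call. = FALSE)
  }
  is_case <- labels == "case"
  m <- sum(is_case); n <- sum(!is_case)
  if (m == 0 || n == 0) stop("both arms must be non-empty", call. = FALSE)
  ca <- delong_components(scores_a[is_case], scores_a[!is_case])
  cb <- delong_components(scores_b[is_case], scores_b[!is_case])
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  variance <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  variance <- max(variance, 0)
  difference <- ca$auc - cb$auc
  degenerate <- FALSE
  if (variance == 0) {
    if (abs(difference) > 0) {
      warning("zero DeLong variance with nonzero AUC difference; p-value set to 0",
              call. = FALSE)
      z <- Inf * sign(difference); p <- 0; degenerate <- TRUE
    } else {
      z <- 0; p <- 1
    }
  } else {
    z <- difference / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    auc_a = ca$auc, auc_b = cb$auc, difference = difference,
    variance = variance,
    ci_low = difference - zq * sqrt(variance),
    ci_high = difference + zq * sqrt(variance),
    z = z, p_value = p, degenerate = degenerate
  ), class = "auc_comparison")
}

#' Empirical ROC curve points
#'
#' One operating point per distinct score threshold (classification rule
#' "score >= threshold is high risk"), thresholds descending, starting at
#' (0, 0) and ending at (1, 1). The trapezoidal area under these points
#' equals [empirical_auc()] (same tie convention).
#'
#' @param cases,controls Raw scores per arm (non-empty).
#' @return Tibble with columns `threshold` (`Inf` for the (0,0) corner),
#'   `fpr` (1 - specificity) and `tpr` (sensitivity).
#' @export
roc_points <- function(cases, controls) {
  if (length(cases) == 0 || length(controls) == 0) {
    stop("both score lists must be non-empty", call. = FALSE)
  }
  thresholds <- sort(unique(c(cases, controls)), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(cases >= t), 0)
  fpr <- vapply(thresholds, function(t) mean(controls >= t), 0)
  tibble::tibble(threshold = c(Inf, thresholds), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under ROC points
#' @param points Tibble from [roc_points()].
#' @return Numeric area.
#' @export
roc_auc_trapezoid <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
}

#' Pairwise DeLong comparisons against a baseline tool
#'
#' Runs [delong_compare()] of every other tool against the baseline on a long
#' score tibble — the AUC-difference table of the validation analysis. Both
#' operands are labelled explicitly: `difference = auc_baseline - auc_tool`.
#'
#' @param scores Long tibble from [score_cohort()].
#' @param baseline Baseline tool name (default `"ripp"`).
#' @param level Confidence level.
#' @return Tibble with one row per comparator.
#' @export
auc_comparison_table <- function(scores, baseline = "ripp", level = 0.95) {
  tools <- setdiff(unique(scores$tool), baseline)
  base <- scores[scores$tool == baseline, ]
  base <- base[order(base$id), ]
  rows <- lapply(tools, function(tool) {
    s <- scores[scores$tool == tool, ]
    s <- s[order(s$id), ]
    if (!identical(s$id, base$id)) {
      stop(sprintf("tool '%s' and baseline '%s' scored different record sets",
                   tool, baseline), call. = FALSE)
    }
    cmp <- delong_compare(base$raw, s$raw, base$arm, level)
    tibble::tibble(
      baseline = baseline, tool = tool,
      auc_baseline = cmp$auc_a, auc_tool = cmp$auc_b,
      difference = cmp$difference, ci_low = cmp$ci_low, ci_high = cmp$ci_high,
      z = cmp$z, p_value = cmp$p_value
    )
  })
  do.call(rbind, rows)
}
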