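# Net reclassification index between two dichotomous classifiers.
#
# "Up" is a move from baseline low risk to candidate high risk; "down" the
# reverse. Among events (cases) upward moves are improvements; among
# non-events (controls) downward moves are. The per-arm (event/non-event)
# convention is used throughout:
#   event_nri    = P(up | case)    - P(down | case)
#   nonevent_nri = P(down | control) - P(up | control)
#   overall_nri  = event_nri + nonevent_nri

#' Net reclassification index
#'
#' Compares a candidate dichotomous classifier against a baseline on paired
#' records, reporting the full four-proportion decomposition with explicit
#' arm labels (rather than two sign-ambiguous columns), the event and
#' non-event components, and the overall NRI. Antisymmetric: swapping
#' baseline and candidate negates the overall NRI.
#'
#' @param baseline Logical high-risk classification per record (baseline tool).
#' @param candidate Logical high-risk classification per record (candidate).
#' @param labels Arm label per record (`case`/`control`), aligned.
#' @return List of class `nri_result`: the four proportions (`p_up_cases`,
#'   `p_down_cases`, `p_up_controls`, `p_down_controls`), their counts,
#'   arm sizes, `event_nri`, `nonevent_nri`, `overall_nri`.
#' @export
nri <- function(baseline, candidate, labels) {
  if (length(baseline) != length(candidate) || length(baseline) != length(labels)) {
    stop("baseline, candidate and labels must be aligned", call. = FALSE)
  }
  is_case <- labels == "case"
  m <- sum(is_case); n <- sum(!is_case)
  if (m == 0 || n == 0) {
    stop("both arms must be non-empty to compute an NRI", call. = FALSE)
  }
  up <- !baseline & candidate
  down <- baseline & !candidate
  n_up_cases <- sum(up & is_case); n_down_cases <- sum(down & is_case)
  n_up_controls <- sum(up & !is_case); n_down_controls <- sum(down & !is_case)
  p_up_cases <- n_up_cases / m; p_down_cases <- n_down_cases / m
  p_up_controls <- n_up_controls / n; p_down_controls <- n_down_controls / n
  event_nri <- p_up_cases - p_down_cases
  nonevent_nri <- p_down_controls - p_up_controls
  structure(list(
    n_cases = m, n_controls = n,
    n_up_cases = n_up_cases, n_down_cases = n_down_cases,
    n_up_controls = n_up_controls, n_down_controls = n_down_controls,
    p_up_cases = p_up_cases, p_down_cases = p_down_cases,
    p_up_controls = p_up_controls, p_down_controls = p_down_controls,
    event_nri = event_nri, nonevent_nri = nonevent_nri,
    overall_nri = event_nri + nonevent_nri
  ), class = "nri_result")
}

#' Reclassification cross-tabulation
#'
#' Per-arm 2x2 counts of (baseline, candidate) classification pairs:
#' low→low, low→high, high→low, high→high. Margins equal arm sizes.
#'
#' @inheritParams nri
#' @return Tibble with columns `arm`, `low_low`, `low_high`, `high_low`,
#'   `high_high`.
#' @export
reclassification_table <- function(baseline, candidate, labels) {
  if (length(baseline) != length(candidate) || length(baseline) != length(labels)) {
    stop("baseline, candidate and labels must be aligned", call. = FALSE)
  }
  one_arm <- function(arm) {
    sel <- labels == arm
    b <- baseline[sel]; c_ <- candidate[sel]
    tibble::tibble(
      arm = arm,
      low_low = sum(!b & !c_), low_high = sum(!b & c_),
      high_low = sum(b & !c_), high_high = sum(b & c_)
    )
  }
  rbind(one_arm("case"), one_arm("control"))
}

#' NRI recomputed from a reclassification table
#'
#' Two-path consistency check: the NRI derived from the cross-tabulation of
#' [reclassification_table()] equals the record-wise [nri()].
#'
#' @param tab Tibble from [reclassification_table()].
#' @return List with `event_nri`, `nonevent_nri`, `overall_nri`.
#' @export
nri_from_table <- function(tab) {
  row <- function(arm) tab[tab$arm == arm, ]
  ca <- row("case"); co <- row("control")
  m <- ca$low_low + ca$low_high + ca$high_low + ca$high_high
  n <- co$low_low + co$low_high + co$high_low + co$high_high
  event_nri <- (ca$low_high - ca$high_low) / m
  nonevent_nri <- (co$high_low - co$low_high) / n
  list(event_nri = event_nri, nonevent_nri = nonevent_nri,
       overall_nri = event_nri + nonevent_nri)
}

#' Pairwise NRI table against a baseline tool
#'
#' Runs [nri()] of every other tool (as candidate) against the baseline on a
#' long score tibble — the reclassification table of the validation analysis.
#'
#' @param scores Long tibble from [score_cohort()].
#' @param baseline Baseline tool name (default `"ripp"`).
#' @return Tibble with one row per comparator.
#' @export
nri_table <- function(scores, baseline = "ripp") {
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
    r <- nri(base$high_risk, s$high_risk, base$arm)
    tibble::tibble(
      baseline = baseline, candidate = tool,
      p_up_cases = r$p_up_cases, p_down_cases = r$p_down_cases,
      p_up_controls = r$p_up_controls, p_down_controls = r$p_down_controls,
      event_nri = r$event_nri, nonevent_nri = r$nonevent_nri,
      overall_nri = r$overall_nri
    )
  })
  do.call(rbind, rows)
}
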