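# Independent oracles, deliberately written in a different style from the
# implementation they check (scalar if-chains, double loops, numerical tail
# inversion). They never call the package's own code paths.

# RIPP scorecard, transcribed item by item for a single record.
oracle_ripp_total <- function(rec) {
  rf <- 0
  if (isTRUE(rec$known_aortic_aneurysm) || isTRUE(rec$known_thoracic_aortic_aneurysm)) {
    rf <- 2
  } else if (isTRUE(rec$family_history) || isTRUE(rec$aortic_manipulation) ||
             isTRUE(rec$aortic_valve_disease) || isTRUE(rec$connective_tissue_disease)) {
    rf <- 1
  }
  imp <- switch(as.character(rec$impression),
                alternative_likely = -1, unsure = 0, aas_most_likely = 2)
  ex <- 0
  if (isTRUE(rec$hypotension) || isTRUE(rec$new_murmur) || isTRUE(rec$pulse_deficit) ||
      isTRUE(rec$focal_neuro_deficit) || isTRUE(rec$bp_differential_gt20)) {
    ex <- 2
  }
  npain <- sum(isTRUE(rec$abrupt_onset_pain), isTRUE(rec$tearing_ripping),
               isTRUE(rec$migrating_radiating), isTRUE(rec$severe_pain))
  pain <- if (npain == 0) 0 else if (npain <= 2) 1 else 2
  rf + imp + ex + pain
}

# Exact binomial interval by direct numerical inversion of the tail
# probabilities (no beta quantiles).
oracle_exact_binom_ci <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lo <- if (x == 0) 0 else {
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo, hi)
}

# Mann-Whitney AUC by brute-force double loop, ties counted one half.
oracle_auc_bruteforce <- function(cases, controls) {
  total <- 0
  for (x in cases) {
    for (y in controls) {
      if (x > y) total <- total + 1 else if (x == y) total <- total + 0.5
    }
  }
  total / (length(cases) * length(controls))
}

# Rank-free AUC used inside bootstrap loops (fast, still independent of the
# package's midrank component machinery).
boot_auc <- function(cases, controls) {
  r <- rank(c(cases, controls), ties.method = "average")
  m <- length(cases)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(controls))
}

# NRI by explicit per-arm counting over a classification pair.
oracle_nri <- function(baseline, candidate, labels) {
  cs <- labels == "case"
  m <- sum(cs); n <- sum(!cs)
  up_c <- sum(!baseline[cs] & candidate[cs])
  down_c <- sum(baseline[cs] & !candidate[cs])
  up_n <- sum(!baseline[!cs] & candidate[!cs])
  down_n <- sum(baseline[!cs] & !candidate[!cs])
  (up_c - down_c) / m + (down_n - up_n) / n
}
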