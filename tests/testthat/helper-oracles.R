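# Independent oracles used across the suite. These stay deliberately
# separate from the implementation paths they check.

# Hand-transcribed LR-3/4/5 decision table over all 24 combinations of
# nonrim APHE x size bin x washout x capsule (threshold growth not modeled).
decision_table_oracle <- function() {
  tbl <- expand.grid(
    aphe = c(FALSE, TRUE),
    bin = c("<10", "10-19", ">=20"),
    washout = c(FALSE, TRUE),
    capsule = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  expected <- character(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    r <- tbl[i, ]
    k <- r$washout + r$capsule
    expected[i] <-
      if (!r$aphe && r$bin != ">=20") c("LR-3", "LR-3", "LR-4")[k + 1]
      else if (!r$aphe) c("LR-3", "LR-4", "LR-4")[k + 1]
      else if (r$bin == "<10") c("LR-3", "LR-4", "LR-4")[k + 1]
      else if (r$bin == "10-19") {
        if (k == 0) "LR-3" else if (r$washout) "LR-5" else "LR-4"
      } else c("LR-4", "LR-5", "LR-5")[k + 1]
  }
  tbl$expected <- expected
  tbl$diameter <- c("<10" = 5, "10-19" = 15, ">=20" = 30)[tbl$bin]
  tbl
}

# Two-sided Fisher p by brute-force enumeration of all tables with the
# observed margins, summing hypergeometric probabilities <= the observed
# table's probability.
fisher_p_enumeration <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(r1 + r2, c1)
  obs <- choose(r1, a) * choose(r2, c) / choose(r1 + r2, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# AUC as the fraction of concordant case/control score pairs (+1/2 ties),
# O(n^2).
auc_pair_count <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A prevalence spec with every group size scaled by `factor`.
scaled_spec <- function(factor = 4L, base = table2_prevalence_spec()) {
  prevalence_spec(base$features, base$diameter_bins,
                  base$n_hcc * factor, base$n_nonhcc * factor,
                  base$agent_hbp)
}
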