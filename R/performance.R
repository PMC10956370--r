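#' Diagnostic performance of an adjustment on LR-3/4 lesions
#'
#' Applies the panel's upgrade/degrade/retain rule to every lesion with a
#' preliminary LR-3 or LR-4 category and summarizes the outcome
#' distribution per diagnostic group. Sensitivity is the proportion of HCC
#' LR-3/4 lesions labeled upgrade; specificity is the proportion of non-HCC
#' LR-3/4 lesions not labeled upgrade.
#'
#' @param cohort a cohort data.frame (categorized on the fly if needed).
#' @param panel an [af_panel()].
#' @return A `performance_report` (see [performance_from_outcomes()]).
#' @export
evaluate_adjustment <- function(cohort, panel) {
  if (!"lr_initial" %in% names(cohort) || !"outcome" %in% names(cohort)) {
    cohort <- categorize_cohort(cohort, panel)
  }
  keep <- cohort$lr_initial %in% c("LR-3", "LR-4")
  sub <- cohort[keep, , drop = FALSE]
  performance_from_outcomes(
    hcc = sub$outcome[sub$group == "HCC"],
    nonhcc = sub$outcome[sub$group == "nonHCC"]
  )
}

#' Performance report from outcome label sequences
#'
#' @param hcc,nonhcc character vectors of `"upgrade"` / `"retain"` /
#'   `"degrade"` labels for the LR-3/4 lesions of each group.
#' @return object of class `performance_report`: `outcome_counts` (3x2
#'   matrix), `sensitivity`, `specificity`, `n_hcc`, `n_nonhcc`. Metrics
#'   are `NA` (flagged via `degenerate`) when a group is empty.
#' @export
performance_from_outcomes <- function(hcc, nonhcc) {
  labels <- c("degrade", "retain", "upgrade")
  stopifnot(all(hcc %in% labels), all(nonhcc %in% labels))
  counts <- cbind(
    HCC = table(factor(hcc, levels = labels)),
    nonHCC = table(factor(nonhcc, levels = labels))
  )
  n_hcc <- length(hcc)
  n_nonhcc <- length(nonhcc)
  structure(list(
    outcome_counts = counts,
    sensitivity = if (n_hcc) counts["upgrade", "HCC"] / n_hcc else NA_real_,
    specificity = if (n_nonhcc) {
      1 - counts["upgrade", "nonHCC"] / n_nonhcc
    } else NA_real_,
    n_hcc = n_hcc, n_nonhcc = n_nonhcc,
    degenerate = n_hcc == 0 || n_nonhcc == 0
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\n")
  print(x$outcome_counts)
  cat(sprintf("  sensitivity %.2f%% (%d/%d), specificity %.2f%% (%d/%d)\n",
              100 * x$sensitivity, x$outcome_counts["upgrade", "HCC"],
              x$n_hcc,
              100 * x$specificity,
              x$n_nonhcc - x$outcome_counts["upgrade", "nonHCC"],
              x$n_nonhcc))
  invisible(x)
}

#' Cohen's kappa for two categorical labelings
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the marginal label products.
#'
#' @param a,b equal-length categorical vectors over a shared vocabulary.
#' @return list `kappa`, `p_o`, `p_e`, `n`; `kappa` is `NA` (flagged
#'   `degenerate`) when `p_e = 1` (both sequences constant and equal).
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label sequences must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 paired labels")
  levels <- sort(unique(c(as.character(a), as.character(b))))
  fa <- factor(a, levels = levels)
  fb <- factor(b, levels = levels)
  p_o <- mean(fa == fb)
  p_e <- sum(prop.table(table(fa)) * prop.table(table(fb)))
  if (1 - p_e < .Machine$double.eps) {
    return(list(kappa = NA_real_, p_o = p_o, p_e = p_e, n = n,
                degenerate = TRUE))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, n = n,
       degenerate = FALSE)
}

#' McNemar test for paired binary outcomes
#'
#' Compares two diagnostic methods on the same lesions from the discordant
#' counts `b` (method 1 correct only) and `c` (method 2 correct only):
#' exact two-sided binomial test `2 P(X <= min(b, c) | b + c, 1/2)` (capped
#' at 1) when `b + c < 25`, otherwise the chi-square statistic `(b - c)^2 /
#' (b + c)` without continuity correction. An optional Bonferroni factor
#' multiplies the p-value (capped at 1) when the test is one of a family,
#' e.g. the sensitivity/specificity pair.
#'
#' @param b,c discordant counts.
#' @param bonferroni multiplicity factor applied to the p-value.
#' @return list `statistic` (`NA` for exact), `p`, `p_adjusted`, `method`,
#'   `degenerate` (`TRUE` when `b + c = 0`, with `p = 1` by convention).
#' @export
mcnemar_test <- function(b, c, bonferroni = 1) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c), bonferroni >= 1)
  nd <- b + c
  if (nd == 0) {
    return(list(statistic = NA_real_, p = 1, p_adjusted = 1,
                method = "degenerate", degenerate = TRUE))
  }
  if (nd < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
    out <- list(statistic = NA_real_, p = p, method = "exact_binomial")
  } else {
    stat <- (b - c)^2 / nd
    out <- list(statistic = stat,
                p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chi_square")
  }
  out$p_adjusted <- min(1, out$p * bonferroni)
  out$degenerate <- FALSE
  out
}

#' Compare two adjustment methods on the same cohort
#'
#' Applies both panels to the LR-3/4 lesions of a categorized cohort and
#' reports per-method sensitivity/specificity, Cohen's kappa between the
#' two outcome-label sequences, and McNemar tests (Bonferroni factor 2) of
#' the paired sensitivity (HCC lesions: upgraded yes/no) and specificity
#' (non-HCC lesions: not-upgraded yes/no) indicators.
#'
#' @param cohort a cohort data.frame.
#' @param panel_a,panel_b two [af_panel()] objects.
#' @return list `report_a`, `report_b`, `kappa`, `mcnemar_sensitivity`,
#'   `mcnemar_specificity`.
#' @export
compare_methods <- function(cohort, panel_a, panel_b) {
  ca <- categorize_cohort(cohort, panel_a)
  cb <- categorize_cohort(cohort, panel_b)
  keep <- ca$lr_initial %in% c("LR-3", "LR-4")
  oa <- ca$outcome[keep]
  ob <- cb$outcome[keep]
  grp <- ca$group[keep]

  disc <- function(correct_a, correct_b) {
    c(b = sum(correct_a & !correct_b), c = sum(!correct_a & correct_b))
  }
  sens <- disc(oa[grp == "HCC"] == "upgrade", ob[grp == "HCC"] == "upgrade")
  spec <- disc(oa[grp == "nonHCC"] != "upgrade",
               ob[grp == "nonHCC"] != "upgrade")
  list(
    report_a = evaluate_adjustment(ca, panel_a),
    report_b = evaluate_adjustment(cb, panel_b),
    kappa = cohens_kappa(oa, ob),
    mcnemar_sensitivity = mcnemar_test(sens["b"], sens["c"], bonferroni = 2),
    mcnemar_specificity = mcnemar_test(spec["b"], spec["c"], bonferroni = 2)
  )
}

#' Stratified train/validation split
#'
#' Splits a binary-labeled set 7:3 (by default) preserving class balance:
#' per-class train counts start at `floor(n_class * train_fraction)` and
#' the remainder needed to reach `round(n * train_fraction)` is assigned by
#' descending fractional part (deterministic); which rows fill each class
#' quota is drawn with the seed.
#'
#' @param labels class label vector (2 classes, each with >= 2 members).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list `train`, `validation`: disjoint, exhaustive index vectors.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  classes <- unique(labels)
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every class needs at least 2 members")
  local_rng(seed)
  raw <- as.numeric(sizes[as.character(classes)]) * train_fraction
  base <- floor(raw)
  extra <- round(length(labels) * train_fraction) - sum(base)
  if (extra > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(extra)]] <- base[order_frac[seq_len(extra)]] + 1
  }
  train <- unlist(lapply(seq_along(classes), function(i) {
    idx <- which(labels == classes[i])
    sample(idx, base[i])
  }))
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

#' AUC by the rank estimator with Hanley-McNeil interval
#'
#' Mann-Whitney AUC with midrank tie handling; the 95% CI uses the
#' Hanley-McNeil variance approximation (truncated to \[0, 1\]).
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (1/TRUE = event).
#' @param conf_mult normal quantile for the interval.
#' @return list `auc`, `ci_low`, `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_mult = stats::qnorm(0.975)) {
  y <- as.logical(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  se <- sqrt(max(v, 0))
  list(auc = auc,
       ci_low = max(0, auc - conf_mult * se),
       ci_high = min(1, auc + conf_mult * se),
       se = se, n_pos = n1, n_neg = n0)
}

#' Decision-curve net benefit
#'
#' Net benefit of classifying positive at probability threshold `t`:
#' `NB(t) = TP/n - FP/n * t / (1 - t)` (positive when probability >= t),
#' with the treat-all and treat-none reference policies.
#'
#' @param probabilities predicted event probabilities.
#' @param labels binary labels (1/TRUE = event).
#' @param thresholds grid in (0, 1); 1 is excluded by construction.
#' @return data.frame `threshold`, `net_benefit`, `nb_all`, `nb_none`.
#' @export
net_benefit <- function(probabilities, labels,
                        thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as.logical(labels)
  stopifnot(length(probabilities) == length(y))
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  n <- length(y)
  prev <- mean(y)
  rows <- vapply(thresholds, function(t) {
    pos <- probabilities >= t
    tp <- sum(pos & y) / n
    fp <- sum(pos & !y) / n
    w <- t / (1 - t)
    c(t, tp - fp * w, prev - (1 - prev) * w, 0)
  }, numeric(4))
  out <- as.data.frame(t(rows))
  names(out) <- c("threshold", "net_benefit", "nb_all", "nb_none")
  out
}

#' Calibration table over equal-width probability bins
#'
#' @param probabilities predicted probabilities in \[0, 1\].
#' @param labels binary labels.
#' @param n_bins number of equal-width bins on \[0, 1\].
#' @return data.frame `bin`, `mean_pred`, `obs_rate`, `n` (empty bins
#'   dropped).
#' @export
calibration_bins <- function(probabilities, labels, n_bins = 10) {
  y <- as.numeric(as.logical(labels))
  if (!length(probabilities)) stop("empty input")
  stopifnot(length(probabilities) == length(y), n_bins >= 1,
            all(probabilities >= 0 & probabilities <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(probabilities, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(bb) {
    idx <- bin == bb
    data.frame(bin = bb, mean_pred = mean(probabilities[idx]),
               obs_rate = mean(y[idx]), n = sum(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Internal 7:3 cross-validation of a screening model
#'
#' Stratified split of the contrast's lesions, refit of the panel's
#' multivariable logistic model on the training part, and evaluation of
#' both parts: ROC/AUC with Hanley-McNeil intervals, calibration bins and
#' decision-curve net benefit on the validation part.
#'
#' @param cohort a cohort data.frame.
#' @param contrast `"all"` or `"lr34"`.
#' @param features AF names to use as predictors (e.g. a screened panel's
#'   selection); defaults to screening the cohort first.
#' @param train_fraction,seed split parameters.
#' @return list `train_auc`, `validation_auc` (each a [roc_auc()] result),
#'   `calibration`, `net_benefit`, `fit`, `split`, `features`.
#' @export
validate_model <- function(cohort, contrast = c("all", "lr34"),
                           features = NULL, train_fraction = 0.7, seed = 1) {
  contrast <- match.arg(contrast)
  sub <- screening_frame(cohort, contrast)
  if (is.null(features)) {
    sp <- screen_panel(cohort, contrast)
    features <- sp$stepwise$selected
  }
  if (!length(features)) stop("no predictor features to validate")
  split <- stratified_split(sub$y, train_fraction, seed)
  x <- as.matrix(as.data.frame(lapply(sub[features], as.numeric),
                               check.names = FALSE))
  colnames(x) <- features
  fit <- fit_logistic(x[split$train, , drop = FALSE], sub$y[split$train])
  p_train <- fit$fitted
  p_val <- predict(fit, x[split$validation, , drop = FALSE])
  list(
    train_auc = roc_auc(p_train, sub$y[split$train]),
    validation_auc = roc_auc(p_val, sub$y[split$validation]),
    calibration = calibration_bins(p_val, sub$y[split$validation]),
    net_benefit = net_benefit(p_val, sub$y[split$validation]),
    fit = fit, split = split, features = features
  )
}
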