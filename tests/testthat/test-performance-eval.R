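test_that("published outcome fixtures yield the published sensitivities", {
  fx <- table5_outcome_fixture("AF-HCC")
  rep_hcc <- performance_from_outcomes(fx$hcc, fx$nonhcc)
  expect_equal(rep_hcc$sensitivity, 113 / 133)
  expect_equal(unname(rep_hcc$outcome_counts["retain", "HCC"]), 20)
  fx2 <- table5_outcome_fixture("AF-LR")
  expect_equal(performance_from_outcomes(fx2$hcc, fx2$nonhcc)$sensitivity,
               114 / 133)
})

test_that("outcome counts are conserved and extreme panels behave as rules imply", {
  cohort <- sample_cohort(table2_prevalence_spec(), 4)
  panel <- af_panel("AF-HCC")
  report <- evaluate_adjustment(cohort, panel)
  expect_equal(sum(report$outcome_counts[, "HCC"]), report$n_hcc)
  expect_equal(sum(report$outcome_counts[, "nonHCC"]), report$n_nonhcc)
  # empty panel: every lesion retains, sensitivity 0
  empty <- evaluate_adjustment(cohort, af_panel("custom"))
  expect_equal(unname(empty$outcome_counts["retain", "HCC"]), empty$n_hcc)
  expect_equal(empty$sensitivity, 0)
  # saturated malignant AF with no benign AFs: sensitivity 1
  sat <- cohort
  sat$restricted_diffusion <- TRUE
  sat$marked_T2 <- FALSE
  sat$hbp_isointensity <- FALSE
  sat$mild_moderate_T2 <- FALSE # keep exclusivity with marked_T2 moot
  rep_sat <- evaluate_adjustment(
    sat, af_panel("custom", malignant_afs = "restricted_diffusion",
                  benign_afs = "marked_T2"))
  expect_equal(rep_sat$sensitivity, 1)
})

test_that("sensitivity is monotone in the malignant AF set", {
  cohort <- sample_cohort(table2_prevalence_spec(), 8)
  benign <- c("marked_T2", "hbp_isointensity")
  mal_sets <- list("restricted_diffusion",
                   c("restricted_diffusion", "mild_moderate_T2"),
                   c("restricted_diffusion", "mild_moderate_T2",
                     "tp_hypointensity", "fat_in_mass"))
  sens <- vapply(mal_sets, function(m) {
    evaluate_adjustment(cohort, af_panel("custom", malignant_afs = m,
                                         benign_afs = benign))$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("kappa matches hand computation, is symmetric and null-centred", {
  expect_equal(cohens_kappa(c("u", "u", "r", "d"),
                            c("u", "u", "r", "d"))$kappa, 1)
  hand <- cohens_kappa(c("up", "up", "ret", "deg"),
                       c("up", "ret", "ret", "deg"))
  expect_equal(hand$p_o, 0.75)
  expect_equal(hand$p_e, 0.3125)
  expect_equal(hand$kappa, 7 / 11, tolerance = 1e-10) # 0.636364
  set.seed(3)
  a <- sample(c("up", "ret", "deg"), 10000, replace = TRUE)
  b <- sample(c("up", "ret", "deg"), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)$kappa), 0.05)
  expect_equal(cohens_kappa(a, b)$kappa, cohens_kappa(b, a)$kappa)
  expect_true(cohens_kappa(rep("up", 5), rep("up", 5))$degenerate)
  expect_error(cohens_kappa("u", character(0)), "equal length")
})

test_that("McNemar switches between exact and chi-square forms", {
  symm <- mcnemar_test(8, 8)
  expect_equal(symm$p, 1)
  expect_equal(symm$method, "exact_binomial")
  exact <- mcnemar_test(15, 3)
  expect_equal(exact$p, 2 * pbinom(3, 18, 0.5), tolerance = 1e-12) # 0.00754
  chi <- mcnemar_test(40, 20)
  expect_equal(chi$statistic, 400 / 60, tolerance = 1e-12)
  expect_equal(chi$method, "chi_square")
  # uncorrected chi-square agrees with the standard implementation
  ref <- mcnemar.test(matrix(c(10, 20, 40, 10), 2), correct = FALSE)
  expect_equal(chi$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(chi$p, ref$p.value, tolerance = 1e-12)
  degen <- mcnemar_test(0, 0)
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
  # Bonferroni factor doubles and caps the p-value
  expect_equal(mcnemar_test(15, 3, bonferroni = 2)$p_adjusted,
               min(1, 2 * exact$p))
})

test_that("stratified split honours the 7:3 bookkeeping", {
  labels <- rep(c("HCC", "nonHCC"), c(311, 162))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_equal(sum(labels[sp$train] == "HCC"), 218)
  expect_equal(sum(labels[sp$train] == "nonHCC"), 113)
  expect_equal(sort(c(sp$train, sp$validation)), seq_along(labels))
  expect_identical(sp, stratified_split(labels, 0.7, seed = 1))
  expect_false(identical(sp$train, stratified_split(labels, 0.7, 2)$train))
  expect_error(stratified_split(labels, 1.0), "strictly between")
  expect_error(stratified_split(c("a", "b"), 0.5), "at least 2")
})

test_that("AUC equals the concordant-pair fraction and handles nulls", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1)
  set.seed(17)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 1) # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_pair_count(scores, labels), tolerance = 1e-12)
  }
  set.seed(29)
  null_auc <- roc_auc(runif(4000), rep(c(0, 1), each = 2000))$auc
  expect_gt(null_auc, 0.47)
  expect_lt(null_auc, 0.53)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  ci <- roc_auc(c(1, 2, 3, 2.5, 3.5, 4), rep(c(0, 1), each = 3))
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
})

test_that("net benefit matches the formula and its limits", {
  p <- c(0.1, 0.3, 0.5, 0.6, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 1)
  nb <- net_benefit(p, y, thresholds = c(0.2, 0.5, 0.7))
  # hand evaluation at t = 0.5: TP = 3, FP = 1
  expect_equal(nb$net_benefit[nb$threshold == 0.5],
               3 / 6 - 1 / 6 * (0.5 / 0.5))
  # at t = 0.2 the positives are {0.3, 0.5, 0.6, 0.8, 0.9}: TP = 3, FP = 2
  expect_equal(nb$net_benefit[nb$threshold == 0.2],
               3 / 6 - 2 / 6 * (0.2 / 0.8))
  # treat-all tends to prevalence as t -> 0
  tiny <- net_benefit(p, y, thresholds = 1e-6)
  expect_equal(tiny$nb_all, mean(y), tolerance = 1e-5)
  # a perfect classifier attains prevalence at any threshold
  perfect <- net_benefit(y, y, thresholds = c(0.25, 0.5, 0.75))
  expect_true(all(abs(perfect$net_benefit - mean(y)) < 1e-12))
  expect_error(net_benefit(p, y, thresholds = 1), "inside")
})

test_that("calibration bins recover observed rates", {
  set.seed(41)
  p <- runif(10000)
  y <- rbinom(10000, 1, p)
  cal <- calibration_bins(p, y)
  expect_true(all(abs(cal$mean_pred - cal$obs_rate) < 0.05))
  expect_equal(sum(cal$n), 10000)
  one <- calibration_bins(rep(0.5, 20), rep(1, 20))
  expect_equal(nrow(one), 1)
  expect_equal(one$obs_rate, 1)
  overall <- calibration_bins(p, y, n_bins = 1)
  expect_equal(overall$obs_rate, mean(y))
  expect_error(calibration_bins(numeric(0), numeric(0)), "empty")
})

test_that("internal validation refits on the training stratum only", {
  cohort <- sample_cohort(scaled_spec(2), 6)
  v <- validate_model(cohort, "all",
                      features = c("restricted_diffusion", "marked_T2",
                                   "hbp_isointensity"),
                      seed = 6)
  expect_true(v$train_auc$auc > 0.5 && v$train_auc$auc <= 1)
  expect_true(v$validation_auc$auc > 0.5)
  expect_equal(length(v$split$train) + length(v$split$validation),
               2 * 473)
  expect_error(validate_model(cohort, "all", features = character()),
               "no predictor")
})
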