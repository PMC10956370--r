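test_that("feature contingency tables match the fixture counts", {
  fx <- marginal_fixture()
  t1 <- feature_contingency(fx, "marked_T2", "all")
  expect_equal(unlist(t1[c("a", "b", "c", "d")], use.names = FALSE),
               c(3, 308, 35, 127))
  t2 <- feature_contingency(fx, "hbp_isointensity", "all")
  expect_equal(unlist(t2[c("a", "b", "c", "d")], use.names = FALSE),
               c(5, 306, 27, 135))
  cohort <- sample_cohort(table2_prevalence_spec(), 2)
  cohort$mosaic <- FALSE
  t3 <- feature_contingency(cohort, "mosaic", "all")
  expect_equal(c(t3$a, t3$c), c(0, 0))
  expect_equal(t3$a + t3$b, 311)
})

test_that("pairwise LR-category contrasts restrict to the two categories", {
  fx <- marginal_fixture()
  fx <- categorize_cohort(fx)
  tab <- feature_contingency(fx, "restricted_diffusion", c("LR-3", "LR-4"))
  expect_equal(tab$a + tab$b, sum(fx$lr_initial == "LR-3"))
  expect_equal(tab$c + tab$d, sum(fx$lr_initial == "LR-4"))
})

test_that("test choice follows the expected-count-below-5 rule", {
  # min expected cell of (3,308;35,127) is 311*38/473 = 24.99 >= 5
  big <- choose_group_test(contingency_table(3, 308, 35, 127))
  expect_equal(big$test, "pearson_chi2")
  # (0,311;1,161): min expected cell < 5
  small <- choose_group_test(contingency_table(0, 311, 1, 161))
  expect_equal(small$test, "fisher_exact")
  symm <- choose_group_test(contingency_table(1, 1, 1, 1))
  expect_equal(symm$p, 1)
  expect_error(choose_group_test(contingency_table(0, 0, 5, 5)),
               "zero margin")
})

test_that("Pearson statistic equals the closed-form cross-product identity", {
  set.seed(7)
  for (i in 1:20) {
    cells <- rpois(4, 40) + 5
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    res <- choose_group_test(tab)
    if (res$test != "pearson_chi2") next
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    N <- sum(cells)
    oracle <- N * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$statistic, oracle, tolerance = 1e-12)
  }
})

test_that("Fisher two-sided p equals hypergeometric enumeration", {
  cases <- list(c(1, 9, 5, 5), c(3, 7, 9, 1), c(0, 10, 4, 6),
                c(2, 2, 2, 2), c(1, 1, 8, 2))
  for (cs in cases) {
    got <- choose_group_test(contingency_table(cs[1], cs[2], cs[3], cs[4]))
    expect_equal(got$test, "fisher_exact")
    expect_equal(got$p, fisher_p_enumeration(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10, label = paste(cs, collapse = ","))
  }
})

test_that("Woolf odds ratios follow the cross-product with log-scale CI", {
  or <- woolf_or(contingency_table(3, 308, 35, 127))
  expect_equal(or$or, (35 * 308) / (3 * 127), tolerance = 1e-12)
  expect_equal(or$se, sqrt(1 / 3 + 1 / 308 + 1 / 35 + 1 / 127),
               tolerance = 1e-12)
  expect_equal(or$ci_low, exp(or$beta - qnorm(0.975) * or$se),
               tolerance = 1e-12)
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)
  # identical proportions give OR 1
  expect_equal(woolf_or(contingency_table(10, 90, 10, 90))$or, 1)
  # zero cells: Haldane-Anscombe correction, flagged; error when disabled
  zc <- woolf_or(contingency_table(0, 311, 15, 147))
  expect_true(zc$corrected)
  expect_true(is.finite(zc$or))
  expect_error(woolf_or(contingency_table(0, 311, 15, 147), haldane = FALSE),
               "Haldane")
})

test_that("single-predictor logistic beta equals the log cross-product OR", {
  fx <- marginal_fixture()
  x <- matrix(as.numeric(fx$marked_T2), ncol = 1,
              dimnames = list(NULL, "marked_T2"))
  fit <- fit_logistic(x, as.numeric(fx$group == "nonHCC"))
  expect_true(fit$converged)
  beta_oracle <- log((35 * 308) / (3 * 127))
  expect_equal(unname(fit$coefficients["marked_T2"]), beta_oracle,
               tolerance = 1e-6 * abs(beta_oracle))
  # and equals the Woolf beta (saturated 2x2 equivalence)
  expect_equal(unname(fit$coefficients["marked_T2"]),
               woolf_or(feature_contingency(fx, "marked_T2"))$beta,
               tolerance = 1e-6)
})

test_that("IRLS agrees with glm on a multivariable fit", {
  set.seed(21)
  n <- 400
  x <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.3),
             c = rbinom(n, 1, 0.5))
  eta <- -0.5 + 1.2 * x[, "a"] - 0.8 * x[, "b"]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-5)
  expect_equal(fit$log_lik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("a null predictor stays near zero in most seeds", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    y <- rbinom(2000, 1, 0.5)
    x <- matrix(rbinom(2000, 1, 0.4), ncol = 1, dimnames = list(NULL, "x"))
    fit <- fit_logistic(x, y)
    if (abs(fit$coefficients["x"]) < 0.15 && fit$p["x"] > 0.05) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("perfect prediction raises the separation flag, not an error", {
  y <- rep(c(0, 1), each = 20)
  x <- matrix(y, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_logistic(x, y)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_error(fit_logistic(matrix(1, 40, 1), y), "constant")
})

test_that("forward stepwise selects an overwhelming single candidate", {
  set.seed(5)
  n <- 600
  y <- rep(0:1, each = n / 2)
  x <- cbind(strong = rbinom(n, 1, ifelse(y == 1, 0.7, 0.1)))
  res <- forward_stepwise(x, y)
  expect_equal(res$selected, "strong")
  expect_equal(res$trace$action[1], "add")
})

test_that("forward stepwise recovers designed features over noise", {
  recovered <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 1000
    y <- rep(0:1, each = 500)
    x <- sapply(1:10, function(j) {
      p <- if (j <= 2) ifelse(y == 1, 0.5, 0.1) else 0.2
      rbinom(n, 1, p)
    })
    colnames(x) <- paste0("f", 1:10)
    sel <- forward_stepwise(x, y)$selected
    if (all(c("f1", "f2") %in% sel)) recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})

test_that("null candidates produce few spurious entries", {
  n_sel <- vapply(1:10, function(seed) {
    set.seed(100 + seed)
    y <- rbinom(400, 1, 0.5)
    x <- matrix(rbinom(400 * 8, 1, 0.3), ncol = 8,
                dimnames = list(NULL, paste0("n", 1:8)))
    length(forward_stepwise(x, y)$selected)
  }, numeric(1))
  # at entry threshold 0.10 the expected number of chance entries per seed
  # is below 1; well under the 2-feature signal of the designed case
  expect_lt(mean(n_sel), 2)
  expect_true(all(n_sel <= 4))
})

test_that("stepwise selection is invariant to row order", {
  cohort <- sample_cohort(table2_prevalence_spec(), 9)
  perm <- sample(nrow(cohort))
  shuffled <- cohort[perm, ]
  attr(shuffled, "provenance") <- attr(cohort, "provenance")
  a <- screen_panel(cohort, "all")
  b <- screen_panel(shuffled, "all")
  expect_equal(a$stepwise$selected, b$stepwise$selected)
})

test_that("screened panels split by prevalence direction", {
  spec <- table2_prevalence_spec()
  cohort <- sample_cohort(scaled_spec(4), 1)
  panel <- screen_panel(cohort, "all")$panel
  expect_true(all(c("marked_T2", "hbp_isointensity") %in% panel$benign_afs))
  expect_true("restricted_diffusion" %in% panel$malignant_afs)
  # direction rule: higher prevalence in HCC => malignant set
  prev <- sapply(panel$malignant_afs, function(f) {
    mean(cohort[[f]][cohort$group == "HCC"]) -
      mean(cohort[[f]][cohort$group == "nonHCC"])
  })
  expect_true(all(prev > 0))
})

test_that("a cohort with no group differences screens to empty panels", {
  spec <- table2_prevalence_spec()
  flat <- spec$features
  flat$p_nonhcc <- flat$p_hcc
  spec_flat <- prevalence_spec(flat, spec$diameter_bins, 311, 162,
                               c(HCC = 0.3, nonHCC = 0.3))
  cohort <- sample_cohort(spec_flat, 13)
  panel <- screen_panel(cohort, "all")$panel
  expect_lte(length(c(panel$malignant_afs, panel$benign_afs)), 1)
})
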