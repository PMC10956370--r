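#' Contingency table for one feature under a contrast
#'
#' Builds the 2x2 table of feature presence/absence in two comparison
#' groups. Contrasts: `"all"` (HCC vs non-HCC over every lesion),
#' `"lr34"` (HCC vs non-HCC restricted to lesions with preliminary LR-3/4;
#' requires an `lr_initial` column, computed on the fly if absent), or a
#' pair of LR categories such as `c("LR-3", "LR-4")` comparing lesions of
#' those preliminary categories regardless of group.
#'
#' @param cohort a cohort data.frame.
#' @param feature a feature column name (MF or AF).
#' @param contrast `"all"`, `"lr34"`, or a length-2 character vector of LR
#'   categories.
#' @return object of class `contingency_table`: counts `a`, `b` (present /
#'   absent in group 1), `c`, `d` (present / absent in group 2) plus group
#'   and feature labels.
#' @export
feature_contingency <- function(cohort, feature, contrast = "all") {
  stopifnot(feature %in% c(mf_vocabulary(), af_vocabulary()))
  if (is.character(contrast) && length(contrast) == 2) {
    if (!"lr_initial" %in% names(cohort)) cohort <- categorize_cohort(cohort)
    stopifnot(all(contrast %in% lr_levels()))
    g1 <- cohort$lr_initial == contrast[1]
    g2 <- cohort$lr_initial == contrast[2]
    labels <- contrast
  } else {
    contrast <- match.arg(contrast, c("all", "lr34"))
    if (contrast == "lr34") {
      if (!"lr_initial" %in% names(cohort)) cohort <- categorize_cohort(cohort)
      keep <- cohort$lr_initial %in% c("LR-3", "LR-4")
      cohort <- cohort[keep, , drop = FALSE]
    }
    g1 <- cohort$group == "HCC"
    g2 <- cohort$group == "nonHCC"
    labels <- c("HCC", "nonHCC")
  }
  if (!any(g1) || !any(g2)) {
    stop("a comparison group is empty under contrast ",
         paste(labels, collapse = " vs "))
  }
  x <- as.logical(cohort[[feature]])
  contingency_table(a = sum(x & g1), b = sum(!x & g1),
                    c = sum(x & g2), d = sum(!x & g2),
                    groups = labels, feature = feature)
}

#' @rdname feature_contingency
#' @param a,b,c,d non-negative counts: feature present/absent in group 1,
#'   present/absent in group 2.
#' @param groups,feature labels.
#' @export
contingency_table <- function(a, b, c, d, groups = c("group1", "group2"),
                              feature = "feature") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(a = a, b = b, c = c, d = d,
                 groups = groups, feature = feature),
            class = "contingency_table")
}

as_matrix_ct <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), 2, 2,
         dimnames = list(tab$groups, c("present", "absent")))
}

#' Choose and run the group-comparison test for a 2x2 table
#'
#' Follows the standard rule for sparse tables: Fisher's exact test
#' (two-sided, by summation of hypergeometric probabilities no larger than
#' the observed table's) when any expected cell count is below 5, otherwise
#' the Pearson chi-square test without continuity correction.
#'
#' @param tab a [contingency_table()].
#' @return list `test` (`"pearson_chi2"` or `"fisher_exact"`), `statistic`
#'   (chi-square value, `NA` for Fisher), `p`.
#' @export
choose_group_test <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  m <- as_matrix_ct(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a zero margin leaves the test undefined")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    list(test = "fisher_exact", statistic = NA_real_,
         p = stats::fisher.test(m)$p.value)
  } else {
    ch <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(test = "pearson_chi2", statistic = unname(ch$statistic),
         p = ch$p.value)
  }
}

#' Odds ratio with Woolf confidence interval
#'
#' Estimates the odds ratio of feature presence in group 2 relative to
#' group 1 (for the default contrast: odds in the non-HCC group over the
#' HCC group), with the Woolf log-odds interval: `se = sqrt(1/a + 1/b + 1/c
#' + 1/d)`, CI `exp(log(OR) +/- z se)` with `z` the exact 97.5% normal
#' quantile, and a Wald p-value. When any cell is zero and
#' `haldane = TRUE`, 0.5 is added to all four cells (Haldane-Anscombe) and
#' the estimate is flagged `corrected`.
#'
#' @param tab a [contingency_table()].
#' @param conf_mult normal quantile for the CI half-width.
#' @param haldane add 0.5 to every cell when a zero cell is present.
#' @return list `or`, `ci_low`, `ci_high`, `beta` (log OR), `se`, `p`,
#'   `corrected`.
#' @export
woolf_or <- function(tab, conf_mult = stats::qnorm(0.975), haldane = TRUE) {
  stopifnot(inherits(tab, "contingency_table"))
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in table; enable `haldane = TRUE` for the ",
           "Haldane-Anscombe 0.5 correction")
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  beta <- log((c * b) / (a * d))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- beta / se
  list(or = exp(beta),
       ci_low = exp(beta - conf_mult * se),
       ci_high = exp(beta + conf_mult * se),
       beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(z)),
       corrected = corrected)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a Bernoulli logistic model by Newton-Raphson / IRLS with an
#' explicit convergence criterion on the score: iteration stops when the
#' maximum absolute gradient of the log-likelihood falls below `tol`.
#' Complete or quasi-complete separation is detected as a coefficient
#' exceeding 15 in absolute value; the fit is then returned with
#' `converged = FALSE` and `separation = TRUE` rather than raising an
#' error, since separated predictors are a routine outcome of screening
#' sparse imaging features.
#'
#' @param x numeric design matrix (without intercept column).
#' @param y binary 0/1 response.
#' @param tol gradient max-norm tolerance (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return object of class `logistic_fit`: `coefficients` (intercept
#'   first), `se`, `z`, `p` (Wald), `log_lik`, `converged`, `separation`,
#'   `n_iter`, `fitted`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  n <- length(y)
  if (nrow(x) != n) stop("nrow(x) must equal length(y)")
  if (ncol(x) > 0) {
    const <- apply(x, 2, function(col) diff(range(col)) == 0)
    if (any(const)) {
      stop("constant predictor(s): ",
           paste(colnames(x)[const] %||% which(const), collapse = ", "))
    }
  }
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")

  beta <- numeric(p)
  separation <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    if (max(abs(beta)) > 15) { separation <- TRUE; break }
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    beta <- beta + step
    iter <- iter + 1L
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  H <- crossprod(X, X * w)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, p))
  z <- beta / se
  log_lik <- sum(stats::dbinom(y, 1, pmin(pmax(mu, 1e-12), 1 - 1e-12),
                               log = TRUE))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    log_lik = log_lik,
    converged = converged && !separation,
    separation = separation,
    n_iter = iter,
    fitted = mu
  ), class = "logistic_fit")
}

#' Predict event probabilities from a logistic fit
#'
#' @param object a [fit_logistic()] result.
#' @param newdata numeric matrix with the same predictor columns the model
#'   was fitted on (no intercept column).
#' @param ... unused.
#' @return vector of fitted probabilities.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata))
  drop(stats::plogis(X %*% object$coefficients))
}

#' Forward stepwise selection by likelihood-ratio entry
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' whose likelihood-ratio test against the current model has the smallest
#' p-value, provided it is below `p_enter`; stops when no candidate
#' qualifies. Candidates whose addition produces a separated fit are passed
#' over at that step. Ties are broken by candidate order, so the procedure
#' is deterministic given the data.
#'
#' @param x 0/1 predictor matrix with named columns (the candidate set).
#' @param y binary response.
#' @param p_enter entry threshold on the LRT p-value (default 0.10).
#' @return object of class `stepwise_result`: `selected` (ordered names),
#'   `trace` data.frame (step, candidate, p_lrt, action), `fit` (the final
#'   [fit_logistic()] model, `NULL` when nothing is selected).
#' @export
forward_stepwise <- function(x, y, p_enter = 0.10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  selected <- character()
  remaining <- colnames(x)
  null_ll <- fit_logistic(x[, 0, drop = FALSE], y)$log_lik
  current_ll <- null_ll
  current_fit <- NULL
  trace <- list()
  step_i <- 0L
  while (length(remaining)) {
    step_i <- step_i + 1L
    ps <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      cand <- remaining[j]
      fit <- fit_logistic(x[, c(selected, cand), drop = FALSE], y)
      if (fit$separation) next
      lrt <- 2 * (fit$log_lik - current_ll)
      ps[j] <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
      fits[[j]] <- fit
    }
    eligible <- which(!is.na(ps) & ps < p_enter)
    if (!length(eligible)) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = step_i, candidate = NA_character_, p_lrt = NA_real_,
        action = "stop", stringsAsFactors = FALSE)
      break
    }
    best <- eligible[which.min(ps[eligible])]
    selected <- c(selected, remaining[best])
    current_fit <- fits[[best]]
    current_ll <- current_fit$log_lik
    trace[[length(trace) + 1L]] <- data.frame(
      step = step_i, candidate = remaining[best], p_lrt = ps[best],
      action = "add", stringsAsFactors = FALSE)
    remaining <- remaining[-best]
  }
  structure(list(selected = selected,
                 trace = do.call(rbind, trace),
                 fit = current_fit),
            class = "stepwise_result")
}

#' Univariable screen of all ancillary features
#'
#' For every AF, builds the contingency table under the contrast, runs the
#' group-comparison test, the Woolf odds ratio (non-HCC over HCC
#' orientation) and a single-predictor logistic fit of the non-HCC
#' indicator, returning one row per feature.
#'
#' @param cohort a cohort data.frame.
#' @param contrast `"all"` or `"lr34"` (see [feature_contingency()]).
#' @param conf_mult CI multiplier passed to [woolf_or()].
#' @return data.frame: `feature`, counts `a`..`d`, `test`, `p_group`, `or`,
#'   `ci_low`, `ci_high`, `beta`, `p_wald`, `separation`.
#' @export
univariable_screen <- function(cohort, contrast = "all",
                               conf_mult = stats::qnorm(0.975)) {
  if (contrast == "lr34" && !"lr_initial" %in% names(cohort)) {
    cohort <- categorize_cohort(cohort)
  }
  rows <- lapply(af_vocabulary(), function(f) {
    tab <- feature_contingency(cohort, f, contrast)
    grp <- choose_group_test_safe(tab)
    or <- woolf_or(tab, conf_mult = conf_mult)
    data.frame(feature = f, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               test = grp$test, p_group = grp$p,
               or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
               beta = or$beta, corrected = or$corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sub <- screening_frame(cohort, contrast)
  wald <- lapply(out$feature, function(f) {
    xf <- matrix(as.numeric(sub[[f]]), ncol = 1,
                 dimnames = list(NULL, f))
    if (diff(range(xf)) == 0) {
      return(list(p = NA_real_, sep = TRUE))
    }
    fit <- fit_logistic(xf, sub$y)
    list(p = unname(fit$p[f]), sep = fit$separation)
  })
  out$p_wald <- vapply(wald, `[[`, numeric(1), "p")
  out$separation <- vapply(wald, `[[`, logical(1), "sep")
  out
}

# Fisher/chi-square choice, returning NA on degenerate (zero-margin) tables
# instead of erroring, so a screen over sparse features can proceed.
choose_group_test_safe <- function(tab) {
  tryCatch(choose_group_test(tab),
           error = function(e) list(test = "degenerate", statistic = NA_real_,
                                    p = NA_real_))
}

# Restrict a cohort to the contrast's rows and attach the screening
# response y = 1 for non-HCC (the orientation under which the published
# benignity-favoring odds ratios are the table cross-products).
screening_frame <- function(cohort, contrast) {
  if (contrast == "lr34") {
    if (!"lr_initial" %in% names(cohort)) cohort <- categorize_cohort(cohort)
    cohort <- cohort[cohort$lr_initial %in% c("LR-3", "LR-4"), , drop = FALSE]
  }
  cohort$y <- as.numeric(cohort$group == "nonHCC")
  cohort
}

#' Screen an ancillary-feature panel from a cohort
#'
#' The full screening pipeline for one contrast: univariable screen, a
#' univariable filter at `p_enter` (on the Wald p of the single-predictor
#' logistic fit; separated features are excluded unless the filter is
#' bypassed), forward stepwise selection by likelihood-ratio entry, and
#' direction assignment — a selected AF joins the malignant set when its
#' prevalence is higher in the HCC group, the benign set otherwise.
#'
#' @param cohort a cohort data.frame.
#' @param contrast `"all"` (panel label AF-HCC) or `"lr34"` (AF-LR).
#' @param p_enter univariable filter and stepwise entry threshold.
#' @param bypass_univariable_filter pass every non-degenerate AF to the
#'   stepwise search regardless of its univariable p.
#' @return object of class `screen_panel`: the [af_panel()] (`panel`), the
#'   stepwise trace (`stepwise`), the univariable table (`univariable`),
#'   the final multivariable [fit_logistic()] model (`fit`) and `contrast`.
#' @export
screen_panel <- function(cohort, contrast = c("all", "lr34"), p_enter = 0.10,
                         bypass_univariable_filter = FALSE) {
  contrast <- match.arg(contrast)
  uni <- univariable_screen(cohort, contrast)
  sub <- screening_frame(cohort, contrast)
  usable <- !vapply(uni$feature, function(f) {
    diff(range(as.numeric(sub[[f]]))) == 0
  }, logical(1))
  candidates <- if (bypass_univariable_filter) {
    uni$feature[usable]
  } else {
    uni$feature[usable & !uni$separation &
                  !is.na(uni$p_wald) & uni$p_wald < p_enter]
  }
  x <- as.matrix(as.data.frame(lapply(sub[candidates], as.numeric),
                               check.names = FALSE))
  if (length(candidates)) colnames(x) <- candidates
  sw <- if (length(candidates)) forward_stepwise(x, sub$y, p_enter)
        else structure(list(selected = character(), trace = NULL, fit = NULL),
                       class = "stepwise_result")
  prev <- prevalence_by_group(sub)
  malignant <- sw$selected[prev[sw$selected, "HCC"] >
                             prev[sw$selected, "nonHCC"]]
  benign <- setdiff(sw$selected, malignant)
  structure(list(
    panel = af_panel("custom", malignant_afs = malignant, benign_afs = benign),
    stepwise = sw,
    univariable = uni,
    fit = sw$fit,
    contrast = contrast,
    label = if (contrast == "all") "AF-HCC" else "AF-LR"
  ), class = "screen_panel")
}

prevalence_by_group <- function(cohort) {
  afs <- af_vocabulary()
  m <- sapply(afs, function(f) {
    c(HCC = mean(cohort[[f]][cohort$group == "HCC"]),
      nonHCC = mean(cohort[[f]][cohort$group == "nonHCC"]))
  })
  t(m)
}

#' @export
print.screen_panel <- function(x, ...) {
  cat(sprintf("<screen_panel: %s (contrast %s)>\n", x$label, x$contrast))
  print(x$panel)
  invisible(x)
}
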