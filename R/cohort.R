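#' Sample a synthetic lesion cohort
#'
#' Draws a cohort of hepatic observations (one row per lesion) with the
#' marginal structure fixed by a [prevalence_spec()]: group sizes as
#' specified; per lesion a diameter bin drawn at the group's bin
#' frequencies, then a diameter uniform within the bin (the >= 20 mm bin
#' spans 20-80 mm); each major and ancillary feature an independent
#' Bernoulli draw at the group prevalence. Two structural constraints are
#' enforced during sampling rather than by post-hoc editing, so that both
#' marginals of each constrained pair are preserved: mutually exclusive AF
#' pairs (mild-moderate vs marked T2 hyperintensity; HBP hypo- vs
#' isointensity) are drawn jointly with zero co-occurrence, and
#' phase-dependent AFs (transitional / hepatobiliary phase) are drawn only
#' for lesions imaged with a hepatobiliary agent, at the conditional
#' probability that reproduces the specified marginal where feasible (see
#' [target_prevalence()]).
#'
#' @param spec a [prevalence_spec()].
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return data.frame of class `lirads_cohort`: columns `lesion_id`,
#'   `group`, `diameter_mm`, the 3 MF columns, the 16 AF columns (logical)
#'   and `agent`; attribute `provenance` records the seed.
#' @export
sample_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "prevalence_spec"))
  local_rng(seed)
  rows <- lapply(c("HCC", "nonHCC"), function(grp) sample_group(spec, grp))
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  as_lirads_cohort(cohort, provenance = sprintf("synthetic-seed-%d", seed))
}

sample_group <- function(spec, grp) {
  n <- if (grp == "HCC") spec$n_hcc else spec$n_nonhcc
  col <- if (grp == "HCC") "p_hcc" else "p_nonhcc"
  p <- stats::setNames(spec$features[[col]], spec$features$feature)

  bin <- sample.int(3L, n, replace = TRUE, prob = spec$diameter_bins[grp, ])
  lo <- c(1, 10, 20)[bin]
  hi <- c(10, 20, 80)[bin]
  diameter <- stats::runif(n, lo, hi)

  agent_frac <- spec$agent_hbp[[grp]]
  hbp_agent <- stats::runif(n) < agent_frac
  q <- conditional_phase_probs(p, names(p), agent_frac)

  feat <- matrix(FALSE, n, length(p), dimnames = list(NULL, names(p)))
  exclusive <- unlist(exclusive_af_pairs())
  for (f in setdiff(names(p), c(exclusive, phase_dependent_afs()))) {
    feat[, f] <- stats::runif(n) < p[[f]]
  }
  # exclusive pairs: one uniform draw split into [0, pA), [pA, pA+pB) strata
  # preserves both marginals with zero co-occurrence
  u <- stats::runif(n)
  feat[, "mild_moderate_T2"] <- u < p[["mild_moderate_T2"]]
  feat[, "marked_T2"] <- u >= p[["mild_moderate_T2"]] &
    u < p[["mild_moderate_T2"]] + p[["marked_T2"]]
  v <- stats::runif(n)
  feat[, "hbp_hypointensity"] <- hbp_agent & v < q[["hbp_hypointensity"]]
  feat[, "hbp_isointensity"] <- hbp_agent & v >= q[["hbp_hypointensity"]] &
    v < q[["hbp_hypointensity"]] + q[["hbp_isointensity"]]
  feat[, "tp_hypointensity"] <- hbp_agent & stats::runif(n) < q[["tp_hypointensity"]]

  build_group_df(grp, n, diameter, feat, hbp_agent)
}

#' Sample a cohort with a shared latent severity factor
#'
#' Variant of [sample_cohort()] in which all binary features load on a
#' single standard-normal latent severity through a Gaussian threshold
#' copula: feature j is present when `sqrt(loading) * z + sqrt(1 - loading)
#' * e_j < qnorm(p_j)`, so marginal prevalences are preserved while features
#' co-occur. Intended for feature-selection recovery experiments where
#' independent features would be unrealistically easy. Exclusivity and
#' phase constraints are enforced afterwards by clearing the commoner
#' feature of a conflicting pair, which can shrink its marginal slightly in
#' this mode.
#'
#' @inheritParams sample_cohort
#' @param loading correlation loading in \[0, 1).
#' @return A `lirads_cohort` data.frame.
#' @export
sample_cohort_correlated <- function(spec, seed, loading = 0.3) {
  stopifnot(inherits(spec, "prevalence_spec"), loading >= 0, loading < 1)
  local_rng(seed)
  rows <- lapply(c("HCC", "nonHCC"), function(grp) {
    n <- if (grp == "HCC") spec$n_hcc else spec$n_nonhcc
    col <- if (grp == "HCC") "p_hcc" else "p_nonhcc"
    p <- stats::setNames(spec$features[[col]], spec$features$feature)

    bin <- sample.int(3L, n, replace = TRUE, prob = spec$diameter_bins[grp, ])
    diameter <- stats::runif(n, c(1, 10, 20)[bin], c(10, 20, 80)[bin])
    agent_frac <- spec$agent_hbp[[grp]]
    hbp_agent <- stats::runif(n) < agent_frac

    z <- stats::rnorm(n)
    feat <- matrix(FALSE, n, length(p), dimnames = list(NULL, names(p)))
    for (f in names(p)) {
      x <- sqrt(loading) * z + sqrt(1 - loading) * stats::rnorm(n)
      feat[, f] <- x < stats::qnorm(p[[f]])
    }
    for (pair in exclusive_af_pairs()) {
      both <- feat[, pair[1]] & feat[, pair[2]]
      commoner <- pair[which.max(p[pair])]
      feat[both, commoner] <- FALSE
    }
    feat[!hbp_agent, phase_dependent_afs()] <- FALSE
    build_group_df(grp, n, diameter, feat, hbp_agent)
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  as_lirads_cohort(cohort,
                   provenance = sprintf("synthetic-correlated-seed-%d", seed))
}

build_group_df <- function(grp, n, diameter, feat, hbp_agent) {
  df <- data.frame(
    lesion_id = sprintf("%s-%04d", grp, seq_len(n)),
    group = grp,
    diameter_mm = diameter,
    stringsAsFactors = FALSE
  )
  for (f in colnames(feat)) df[[f]] <- feat[, f]
  df$agent <- ifelse(hbp_agent, "hepatobiliary", "extracellular")
  df
}

as_lirads_cohort <- function(df, provenance) {
  attr(df, "provenance") <- provenance
  class(df) <- c("lirads_cohort", "data.frame")
  validate_cohort(df)
  df
}

#' Validate a lesion cohort table
#'
#' Checks the cohort schema and the per-record invariants: positive
#' diameters, unique lesion ids, mutually exclusive AF pairs never jointly
#' present, and phase-dependent AFs absent under an extracellular agent.
#'
#' @param cohort a cohort data.frame.
#' @return The cohort, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort) {
  needed <- c("lesion_id", "group", "diameter_mm",
              mf_vocabulary(), af_vocabulary(), "agent")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0) stop("cohort is empty")
  if (anyDuplicated(cohort$lesion_id)) {
    stop("duplicate lesion_id: ",
         cohort$lesion_id[anyDuplicated(cohort$lesion_id)])
  }
  if (!all(cohort$group %in% c("HCC", "nonHCC"))) {
    stop("group must be 'HCC' or 'nonHCC'")
  }
  if (any(!is.finite(cohort$diameter_mm)) || any(cohort$diameter_mm <= 0)) {
    stop("diameter_mm must be positive and finite")
  }
  if (!all(cohort$agent %in% c("hepatobiliary", "extracellular"))) {
    stop("agent must be 'hepatobiliary' or 'extracellular'")
  }
  for (pair in exclusive_af_pairs()) {
    if (any(cohort[[pair[1]]] & cohort[[pair[2]]])) {
      stop(pair[1], " and ", pair[2], " are mutually exclusive")
    }
  }
  extracell <- cohort$agent == "extracellular"
  for (f in phase_dependent_afs()) {
    if (any(extracell & cohort[[f]])) {
      stop(f, " recorded under an extracellular agent (phase does not exist)")
    }
  }
  invisible(cohort)
}

#' Deterministic cohort reproducing the published marginal counts
#'
#' Builds a cohort whose per-feature per-group counts equal the published
#' frequency table exactly: within each group, each feature is assigned to a
#' deterministic block of lesions whose size is the printed numerator
#' (mutually exclusive pair members are placed at opposite ends of the
#' group). The joint structure across features is therefore an arbitrary but
#' deterministic artifact, intended for exact contingency-table tests, not
#' for model fitting. Lesions carrying a phase-dependent AF are assigned the
#' hepatobiliary agent (topped up toward the specified agent fraction), so
#' the fixture's agent mix can deviate from the specification.
#'
#' @param spec a [prevalence_spec()] whose prevalences are exact count
#'   fractions of the group sizes.
#' @return A `lirads_cohort` data.frame.
#' @export
marginal_fixture <- function(spec = table2_prevalence_spec()) {
  stopifnot(inherits(spec, "prevalence_spec"))
  rows <- lapply(c("HCC", "nonHCC"), function(grp) {
    n <- if (grp == "HCC") spec$n_hcc else spec$n_nonhcc
    col <- if (grp == "HCC") "p_hcc" else "p_nonhcc"
    p <- stats::setNames(spec$features[[col]], spec$features$feature)
    k <- p * n
    if (any(abs(k - round(k)) > 1e-6)) {
      bad <- names(p)[abs(k - round(k)) > 1e-6][1]
      stop("prevalence of ", bad, " does not imply an integer count in ", grp)
    }
    k <- stats::setNames(as.integer(round(k)), names(p))

    kd <- spec$diameter_bins[grp, ] * n
    if (any(abs(kd - round(kd)) > 1e-6)) {
      stop("diameter-bin frequencies do not imply integer counts in ", grp)
    }
    kd <- as.integer(round(kd))
    diameter <- rep(c(5, 15, 30), kd)

    feat <- matrix(FALSE, n, length(p), dimnames = list(NULL, names(p)))
    tail_members <- vapply(exclusive_af_pairs(), function(pair) {
      pair[which.min(k[pair])]
    }, character(1))
    for (f in names(p)) {
      if (k[[f]] == 0) next
      idx <- if (f %in% tail_members) seq.int(n - k[[f]] + 1L, n)
             else seq_len(k[[f]])
      feat[idx, f] <- TRUE
    }
    for (pair in exclusive_af_pairs()) {
      if (sum(k[pair]) > n) {
        stop("exclusive pair ", paste(pair, collapse = "/"),
             " cannot fit disjointly in group ", grp)
      }
    }

    hbp_agent <- rowSums(feat[, phase_dependent_afs(), drop = FALSE]) > 0
    top_up <- round(spec$agent_hbp[[grp]] * n) - sum(hbp_agent)
    if (top_up > 0) {
      free <- which(!hbp_agent)
      hbp_agent[free[seq_len(min(top_up, length(free)))]] <- TRUE
    }
    build_group_df(grp, n, diameter, feat, hbp_agent)
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  as_lirads_cohort(cohort, provenance = "fixture-marginal-counts")
}

#' Deterministic adjustment-outcome fixture
#'
#' Returns, for each diagnostic group, the sequence of upgrade / retain /
#' degrade outcome labels among LR-3/4 lesions whose counts equal the
#' published distribution of the corresponding adjustment method: with the
#' panel screened from all lesions (`"AF-HCC"`), 0/20/113
#' degrade/retain/upgrade of 133 HCC lesions and 16/72/61 of 149 non-HCC
#' lesions; with the panel screened from LR-3/4 lesions only (`"AF-LR"`),
#' 1/18/114 and 14/65/70.
#'
#' @param method `"AF-HCC"` or `"AF-LR"`.
#' @return list with character vectors `hcc` and `nonhcc` of outcome labels.
#' @export
table5_outcome_fixture <- function(method = c("AF-HCC", "AF-LR")) {
  method <- match.arg(method)
  counts <- switch(method,
    "AF-HCC" = list(hcc = c(degrade = 0, retain = 20, upgrade = 113),
                    nonhcc = c(degrade = 16, retain = 72, upgrade = 61)),
    "AF-LR" = list(hcc = c(degrade = 1, retain = 18, upgrade = 114),
                   nonhcc = c(degrade = 14, retain = 65, upgrade = 70))
  )
  lapply(counts, function(k) rep(names(k), k))
}

# Seed the RNG for the calling function and restore the previous global
# stream when that function exits.
local_rng <- function(seed, env = parent.frame()) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite integer")
  }
  restore <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    bquote(assign(".Random.seed", .(get(".Random.seed", globalenv())),
                  envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}
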