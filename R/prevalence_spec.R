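#' Construct a prevalence specification for cohort synthesis
#'
#' A `prevalence_spec` fixes everything the synthetic cohort generator needs:
#' per-feature prevalences in each diagnostic group (HCC / non-HCC), lesion
#' diameter-bin frequencies per group, group sizes, and the fraction of each
#' group imaged with a hepatobiliary contrast agent.
#'
#' @param features data.frame with columns `feature`, `p_hcc`, `p_nonhcc`;
#'   one row per major or ancillary feature, probabilities in \[0, 1\].
#' @param diameter_bins numeric matrix with rows `HCC`, `nonHCC` and columns
#'   `<10`, `10-19`, `>=20`; each row must sum to 1 (tolerance 1e-9).
#' @param n_hcc,n_nonhcc positive integer group sizes.
#' @param agent_hbp named numeric vector `c(HCC = , nonHCC = )`: fraction of
#'   lesions in each group imaged with a hepatobiliary agent.
#' @return An object of class `prevalence_spec`.
#' @seealso [table2_prevalence_spec()] for the published defaults.
#' @export
prevalence_spec <- function(features, diameter_bins, n_hcc, n_nonhcc, agent_hbp) {
  stopifnot(is.data.frame(features),
            all(c("feature", "p_hcc", "p_nonhcc") %in% names(features)))
  probs <- c(features$p_hcc, features$p_nonhcc, agent_hbp)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all prevalences and agent fractions must be probabilities in [0, 1]")
  }
  if (anyDuplicated(features$feature)) stop("duplicate feature names in spec")
  known <- c(mf_vocabulary(), af_vocabulary())
  unknown <- setdiff(features$feature, known)
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  diameter_bins <- as.matrix(diameter_bins)
  if (!identical(dim(diameter_bins), c(2L, 3L))) {
    stop("diameter_bins must be a 2 x 3 matrix (groups x bins)")
  }
  if (any(diameter_bins < 0) || any(abs(rowSums(diameter_bins) - 1) > 1e-9)) {
    stop("each group's diameter-bin frequencies must be non-negative and sum to 1")
  }
  if (n_hcc < 1 || n_nonhcc < 1 ||
      n_hcc != round(n_hcc) || n_nonhcc != round(n_nonhcc)) {
    stop("group sizes must be positive integers")
  }
  if (!all(c("HCC", "nonHCC") %in% names(agent_hbp))) {
    stop("agent_hbp must be named c(HCC = , nonHCC = )")
  }
  rownames(diameter_bins) <- c("HCC", "nonHCC")
  colnames(diameter_bins) <- c("<10", "10-19", ">=20")
  structure(
    list(
      features = features[, c("feature", "p_hcc", "p_nonhcc")],
      diameter_bins = diameter_bins,
      n_hcc = as.integer(n_hcc),
      n_nonhcc = as.integer(n_nonhcc),
      agent_hbp = agent_hbp[c("HCC", "nonHCC")]
    ),
    class = "prevalence_spec"
  )
}

#' Published default prevalence specification
#'
#' Per-feature prevalences equal to the published per-group counts of the
#' study cohort (311 HCC and 162 non-HCC lesions): e.g. marked T2
#' hyperintensity in 3/311 HCC vs 35/162 non-HCC lesions, restricted
#' diffusion in 271/311 vs 95/162. Diameter-bin frequencies and the
#' per-group hepatobiliary-agent fractions (98/302 and 40/158, recorded at
#' patient level) come from the same cohort description.
#'
#' @return A [prevalence_spec()] object.
#' @export
table2_prevalence_spec <- function() {
  counts <- data.frame(
    feature = c(mf_vocabulary(), af_vocabulary()),
    k_hcc = c(
      248, 186, 177,                     # APHE, washout, capsule
      252, 28, 15, 32, 79, 80, 271,      # malignancy-in-general AFs
      3, 36, 55, 95, 42,                 # HCC-in-particular AFs
      3, 11, 3, 5                        # benignity AFs
    ),
    k_nonhcc = c(
      90, 17, 18,
      81, 16, 1, 16, 21, 24, 95,
      0, 0, 0, 18, 6,
      15, 1, 35, 27
    )
  )
  features <- data.frame(
    feature = counts$feature,
    p_hcc = counts$k_hcc / 311,
    p_nonhcc = counts$k_nonhcc / 162
  )
  prevalence_spec(
    features = features,
    diameter_bins = rbind(
      HCC = c(13, 78, 220) / 311,
      nonHCC = c(41, 68, 53) / 162
    ),
    n_hcc = 311L,
    n_nonhcc = 162L,
    agent_hbp = c(HCC = 98 / 302, nonHCC = 40 / 158)
  )
}

#' Attainable marginal prevalences of the generator
#'
#' The sampler preserves each specified marginal prevalence exactly except
#' where the specification is jointly infeasible: phase-dependent AFs are
#' only observable in the hepatobiliary-agent stratum, so their attainable
#' marginal is capped at the agent fraction, and a mutually exclusive pair
#' whose within-stratum probabilities sum above 1 is rescaled
#' proportionally. This function returns the marginals the generator
#' actually targets, for use in convergence checks and documentation.
#'
#' @param spec a [prevalence_spec()].
#' @return data.frame `feature`, `p_hcc`, `p_nonhcc` of attainable marginals.
#' @export
target_prevalence <- function(spec) {
  stopifnot(inherits(spec, "prevalence_spec"))
  out <- spec$features
  for (grp in c("HCC", "nonHCC")) {
    col <- if (grp == "HCC") "p_hcc" else "p_nonhcc"
    frac <- spec$agent_hbp[[grp]]
    q <- conditional_phase_probs(out[[col]], out$feature, frac)
    out[[col]] <- ifelse(out$feature %in% phase_dependent_afs(),
                         q * frac, out[[col]])
  }
  out
}

# Within-stratum probabilities for phase-dependent AFs: cap at 1 and rescale
# the exclusive HBP pair if needed. `p` is aligned with `feature`.
conditional_phase_probs <- function(p, feature, agent_frac) {
  q <- ifelse(feature %in% phase_dependent_afs(),
              if (agent_frac > 0) pmin(1, p / agent_frac) else 0,
              p)
  hbp <- match(c("hbp_hypointensity", "hbp_isointensity"), feature)
  if (!anyNA(hbp)) {
    s <- sum(q[hbp])
    if (s > 1) q[hbp] <- q[hbp] / s
  }
  stats::setNames(q, feature)
}

#' @export
print.prevalence_spec <- function(x, ...) {
  cat("<prevalence_spec>\n")
  cat(sprintf("  groups: %d HCC / %d non-HCC lesions\n", x$n_hcc, x$n_nonhcc))
  cat(sprintf("  features: %d (%d MF, %d AF)\n", nrow(x$features),
              sum(x$features$feature %in% mf_vocabulary()),
              sum(x$features$feature %in% af_vocabulary())))
  cat(sprintf("  hepatobiliary agent: %.1f%% HCC, %.1f%% non-HCC\n",
              100 * x$agent_hbp[["HCC"]], 100 * x$agent_hbp[["nonHCC"]]))
  invisible(x)
}

#' Read / write a prevalence specification as JSON
#'
#' @param spec a [prevalence_spec()].
#' @param path file path.
#' @return `write_spec_json` returns `path` invisibly; `read_spec_json`
#'   returns a [prevalence_spec()].
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "prevalence_spec"))
  obj <- list(
    features = spec$features,
    diameter_bins = list(
      HCC = as.numeric(spec$diameter_bins["HCC", ]),
      nonHCC = as.numeric(spec$diameter_bins["nonHCC", ])
    ),
    n_hcc = spec$n_hcc, n_nonhcc = spec$n_nonhcc,
    agent_hbp = as.list(spec$agent_hbp)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prevalence_spec(
    features = as.data.frame(obj$features),
    diameter_bins = rbind(HCC = obj$diameter_bins$HCC,
                          nonHCC = obj$diameter_bins$nonHCC),
    n_hcc = obj$n_hcc, n_nonhcc = obj$n_nonhcc,
    agent_hbp = unlist(obj$agent_hbp)
  )
}
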