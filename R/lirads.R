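#' Diameter size bin
#'
#' Bins a lesion diameter into the three size strata of the LR-3/4/5
#' decision table, with left-closed bins: \[0, 10), \[10, 20), \[20, Inf) mm
#' (so a reported 10 mm lesion falls in the 10-19 mm stratum, matching
#' integer-millimetre clinical reporting).
#'
#' @param diameter_mm positive lesion diameter(s) in millimetres.
#' @return factor with levels `"<10"`, `"10-19"`, `">=20"`.
#' @export
size_bin <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    stop("diameter_mm must be positive and finite")
  }
  cut(diameter_mm, breaks = c(0, 10, 20, Inf), right = FALSE,
      labels = c("<10", "10-19", ">=20"))
}

#' Preliminary LI-RADS category from major features
#'
#' Assigns LR-3 / LR-4 / LR-5 from the v2018 decision table using nonrim
#' APHE, lesion diameter, and the count of additional major features among
#' nonperipheral washout and enhancing capsule. Threshold growth is not
#' modeled (growth features require a follow-up window this analysis
#' excludes), so with nonrim APHE at 10-19 mm a single additional feature
#' reaches LR-5 only when it is washout; capsule alone gives LR-4.
#'
#' @param aphe_nonrim,washout_nonperipheral,capsule_enhancing logical
#'   vectors (recycled to a common length).
#' @param diameter_mm positive diameters in mm.
#' @return character vector of `"LR-3"`, `"LR-4"`, `"LR-5"`.
#' @export
categorize_mf <- function(aphe_nonrim, washout_nonperipheral,
                          capsule_enhancing, diameter_mm) {
  n <- max(length(aphe_nonrim), length(washout_nonperipheral),
           length(capsule_enhancing), length(diameter_mm))
  aphe <- rep_len(as.logical(aphe_nonrim), n)
  washout <- rep_len(as.logical(washout_nonperipheral), n)
  capsule <- rep_len(as.logical(capsule_enhancing), n)
  bin <- as.character(size_bin(rep_len(diameter_mm, n)))
  if (anyNA(aphe) || anyNA(washout) || anyNA(capsule)) {
    stop("major-feature flags must be TRUE/FALSE without NA")
  }
  k <- washout + capsule
  out <- character(n)
  no_aphe <- !aphe
  out[no_aphe & bin != ">=20"] <- ifelse(k[no_aphe & bin != ">=20"] == 2,
                                         "LR-4", "LR-3")
  out[no_aphe & bin == ">=20"] <- ifelse(k[no_aphe & bin == ">=20"] >= 1,
                                         "LR-4", "LR-3")
  out[aphe & bin == "<10"] <- ifelse(k[aphe & bin == "<10"] >= 1,
                                     "LR-4", "LR-3")
  mid <- aphe & bin == "10-19"
  out[mid] <- ifelse(k[mid] == 0, "LR-3",
                     ifelse(washout[mid], "LR-5", "LR-4"))
  out[aphe & bin == ">=20"] <- ifelse(k[aphe & bin == ">=20"] >= 1,
                                      "LR-5", "LR-4")
  out
}

#' Construct an ancillary-feature panel
#'
#' A panel names the AFs treated as favoring malignancy and those favoring
#' benignity when adjusting an LR-3/4 category. `af_panel("AF-HCC")` and
#' `af_panel("AF-LR")` return the two published panels (screened from all
#' lesions and from LR-3/4 lesions respectively); both share the benign AFs
#' marked T2 hyperintensity and HBP isointensity.
#'
#' @param label `"AF-HCC"`, `"AF-LR"`, or `"custom"`.
#' @param malignant_afs,benign_afs character vectors of AF names (required
#'   for `"custom"`; ignored otherwise).
#' @return object of class `af_panel` with elements `malignant_afs`,
#'   `benign_afs`, `label`.
#' @export
af_panel <- function(label = c("AF-HCC", "AF-LR", "custom"),
                     malignant_afs = NULL, benign_afs = NULL) {
  label <- match.arg(label)
  if (label == "AF-HCC") {
    malignant_afs <- c("mild_moderate_T2", "restricted_diffusion",
                       "tp_hypointensity")
    benign_afs <- c("marked_T2", "hbp_isointensity")
  } else if (label == "AF-LR") {
    malignant_afs <- c("restricted_diffusion", "mosaic", "fat_in_mass")
    benign_afs <- c("marked_T2", "hbp_isointensity")
  }
  malignant_afs <- as.character(malignant_afs %||% character())
  benign_afs <- as.character(benign_afs %||% character())
  unknown <- setdiff(c(malignant_afs, benign_afs), af_vocabulary())
  if (length(unknown)) {
    stop("unknown AF name(s): ", paste(unknown, collapse = ", "))
  }
  if (length(intersect(malignant_afs, benign_afs))) {
    stop("malignant and benign AF sets must be disjoint")
  }
  structure(list(malignant_afs = malignant_afs, benign_afs = benign_afs,
                 label = label),
            class = "af_panel")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.af_panel <- function(x, ...) {
  cat(sprintf("<af_panel: %s>\n", x$label))
  cat("  malignant:", paste(x$malignant_afs, collapse = ", "), "\n")
  cat("  benign:   ", paste(x$benign_afs, collapse = ", "), "\n")
  invisible(x)
}

#' Panel flags for a lesion
#'
#' @param lesion one-row cohort data.frame (or list) with the 16 AF columns.
#' @param panel an [af_panel()].
#' @return logical vector `c(has_malignant = , has_benign = )`: whether any
#'   panel AF of each direction is present in the lesion.
#' @export
af_flags <- function(lesion, panel) {
  stopifnot(inherits(panel, "af_panel"))
  present <- function(afs) {
    if (!length(afs)) return(FALSE)
    missing <- setdiff(afs, names(lesion))
    if (length(missing)) stop("lesion lacks AF column(s): ",
                              paste(missing, collapse = ", "))
    any(vapply(afs, function(f) isTRUE(as.logical(lesion[[f]][1])), logical(1)))
  }
  c(has_malignant = present(panel$malignant_afs),
    has_benign = present(panel$benign_afs))
}

#' Apply the one-step category adjustment rule
#'
#' Adjusts a preliminary LR-3 or LR-4 category from the panel flags: only
#' malignant AFs present -> "upgrade" (one step up, capped below LR-5, so an
#' upgraded LR-4 lesion stays LR-4 but is still recorded as upgraded); only
#' benign AFs present -> "degrade" (one step down; a degraded LR-3 becomes
#' LR-2); both or neither -> "retain". LR-5 lesions are outside the rule's
#' domain.
#'
#' @param initial `"LR-3"` or `"LR-4"`.
#' @param has_malignant,has_benign logicals (e.g. from [af_flags()]).
#' @return list `initial`, `outcome` ("upgrade"/"retain"/"degrade"), `final`.
#' @export
adjust_category <- function(initial, has_malignant, has_benign) {
  if (!initial %in% c("LR-3", "LR-4")) {
    stop("adjustment applies only to LR-3/LR-4 lesions, got ", initial)
  }
  levels <- lr_levels()
  i <- match(initial, levels)
  if (has_malignant && !has_benign) {
    outcome <- "upgrade"
    final <- levels[min(i + 1L, match("LR-4", levels))]
  } else if (has_benign && !has_malignant) {
    outcome <- "degrade"
    final <- levels[i - 1L]
  } else {
    outcome <- "retain"
    final <- initial
  }
  list(initial = initial, outcome = outcome, final = final)
}

#' Categorize and adjust a whole cohort
#'
#' Adds to the cohort the preliminary MF-based category (`lr_initial`), the
#' adjustment outcome under the given panel (`outcome`, for LR-3/4 lesions;
#' `NA` for LR-5), the adjusted category (`lr_final`; LR-5 lesions keep
#' LR-5), and the comma-separated panel AFs present in each lesion
#' (`triggering_afs`).
#'
#' @param cohort a cohort data.frame (see [sample_cohort()]).
#' @param panel an [af_panel()]; `NULL` categorizes only.
#' @return the cohort with columns `lr_initial`, `outcome`, `lr_final`,
#'   `triggering_afs` appended.
#' @export
categorize_cohort <- function(cohort, panel = NULL) {
  validate_cohort(cohort)
  cohort$lr_initial <- categorize_mf(cohort$aphe_nonrim,
                                     cohort$washout_nonperipheral,
                                     cohort$capsule_enhancing,
                                     cohort$diameter_mm)
  if (is.null(panel)) return(cohort)
  stopifnot(inherits(panel, "af_panel"))
  panel_afs <- c(panel$malignant_afs, panel$benign_afs)
  af <- as.matrix(cohort[, af_vocabulary(), drop = FALSE])
  has_mal <- if (length(panel$malignant_afs)) {
    rowSums(af[, panel$malignant_afs, drop = FALSE]) > 0
  } else rep(FALSE, nrow(cohort))
  has_ben <- if (length(panel$benign_afs)) {
    rowSums(af[, panel$benign_afs, drop = FALSE]) > 0
  } else rep(FALSE, nrow(cohort))

  adjustable <- cohort$lr_initial %in% c("LR-3", "LR-4")
  cohort$outcome <- NA_character_
  cohort$outcome[adjustable & has_mal & !has_ben] <- "upgrade"
  cohort$outcome[adjustable & !has_mal & has_ben] <- "degrade"
  cohort$outcome[adjustable & (has_mal == has_ben)] <- "retain"
  idx <- match(cohort$lr_initial, lr_levels())
  final_idx <- idx
  final_idx[adjustable] <- idx[adjustable] +
    ifelse(cohort$outcome[adjustable] == "upgrade",
           ifelse(cohort$lr_initial[adjustable] == "LR-3", 1L, 0L),
           ifelse(cohort$outcome[adjustable] == "degrade", -1L, 0L))
  cohort$lr_final <- lr_levels()[final_idx]
  cohort$triggering_afs <- apply(
    af[, panel_afs, drop = FALSE], 1L,
    function(row) paste(panel_afs[as.logical(row)], collapse = ",")
  )
  cohort
}
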