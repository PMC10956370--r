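#' Ancillary-feature vocabulary
#'
#' The 16 binary ancillary features (AFs) tracked per lesion. Growth-related
#' AFs (threshold growth, size stability, size reduction) are excluded from
#' the analysis because they require a >= 24-month follow-up window.
#'
#' @return Character vector of the 16 AF column names.
#' @export
af_vocabulary <- function() {
  c(
    "mild_moderate_T2", "fat_sparing", "iron_sparing", "corona_enhancement",
    "tp_hypointensity", "hbp_hypointensity", "restricted_diffusion",
    "nodule_in_nodule", "mosaic", "blood_products", "fat_in_mass",
    "nonenhancing_capsule", "parallel_blood_pool", "undistorted_vessels",
    "marked_T2", "hbp_isointensity"
  )
}

#' Major-feature vocabulary
#'
#' Binary major features (MFs) entering the LR-3/4/5 decision table, besides
#' lesion diameter: nonrim arterial-phase hyperenhancement, nonperipheral
#' washout and enhancing capsule.
#'
#' @return Character vector of the 3 MF column names.
#' @export
mf_vocabulary <- function() {
  c("aphe_nonrim", "washout_nonperipheral", "capsule_enhancing")
}

# Pairs of AFs that cannot co-occur on one lesion (a lesion is either mildly
# or markedly T2 hyperintense; either hypo- or isointense in the HBP).
exclusive_af_pairs <- function() {
  list(
    c("mild_moderate_T2", "marked_T2"),
    c("hbp_hypointensity", "hbp_isointensity")
  )
}

# AFs only observable when a hepatobiliary contrast agent was given (the
# transitional and hepatobiliary phases do not exist with extracellular
# agents).
phase_dependent_afs <- function() {
  c("tp_hypointensity", "hbp_hypointensity", "hbp_isointensity")
}

# Ordered LI-RADS categories reachable in this pipeline.
lr_levels <- function() c("LR-2", "LR-3", "LR-4", "LR-5")
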