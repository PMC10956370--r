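#' Write / read a cohort as CSV
#'
#' Schema: `lesion_id,group,diameter_mm,<3 MF columns>,<16 AF columns>,
#' agent`, booleans encoded 0/1, UTF-8, `.` decimal separator. Reading
#' validates the schema and every record invariant and reports the first
#' offending row.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a validated `lirads_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[, c("lesion_id", "group", "diameter_mm",
                    mf_vocabulary(), af_vocabulary(), "agent")]
  for (f in c(mf_vocabulary(), af_vocabulary())) {
    out[[f]] <- as.integer(out[[f]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  needed <- c("lesion_id", "group", "diameter_mm",
              mf_vocabulary(), af_vocabulary(), "agent")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  diameter <- suppressWarnings(as.numeric(raw$diameter_mm))
  if (anyNA(diameter)) {
    stop("non-numeric diameter_mm at row ", which(is.na(diameter))[1])
  }
  raw$diameter_mm <- diameter
  for (f in c(mf_vocabulary(), af_vocabulary())) {
    bad <- !raw[[f]] %in% c("0", "1")
    if (any(bad)) {
      stop("column ", f, " must be 0/1; offending row ", which(bad)[1])
    }
    raw[[f]] <- raw[[f]] == "1"
  }
  as_lirads_cohort(raw, provenance = paste0("csv:", basename(path)))
}

#' Pipeline run configuration
#'
#' Exactly one input mode: simulate from a [prevalence_spec()] with a seed,
#' or load a cohort CSV. Defaults mirror the published analysis settings
#' (entry threshold 0.10, 7:3 split, 95% Wald intervals).
#'
#' @param spec a [prevalence_spec()] (simulate mode), or `NULL`.
#' @param csv path to a cohort CSV (csv mode), or `NULL`.
#' @param seed integer seed used for simulation and the validation split.
#' @param p_enter stepwise entry / univariable filter threshold.
#' @param bypass_univariable_filter see [screen_panel()].
#' @param train_fraction internal-validation split fraction.
#' @param thresholds decision-curve threshold grid.
#' @param out_dir output directory for [run_pipeline()] artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(spec = NULL, csv = NULL, seed = 1, p_enter = 0.10,
                       bypass_univariable_filter = FALSE,
                       train_fraction = 0.7,
                       thresholds = seq(0.01, 0.99, by = 0.01),
                       out_dir = tempfile("lirads_run_")) {
  if (is.null(spec) == is.null(csv)) {
    stop("exactly one input mode: give `spec` (simulate) or `csv` (load)")
  }
  structure(list(spec = spec, csv = csv, seed = seed, p_enter = p_enter,
                 bypass_univariable_filter = bypass_univariable_filter,
                 train_fraction = train_fraction, thresholds = thresholds,
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  digestible <- list(
    mode = if (is.null(config$csv)) "simulate" else "csv",
    csv = config$csv,
    spec = if (!is.null(config$spec)) unclass(config$spec),
    seed = config$seed, p_enter = config$p_enter,
    bypass = config$bypass_univariable_filter,
    train_fraction = config$train_fraction,
    thresholds = config$thresholds
  )
  jsonlite::write_json(digestible, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> categorize -> screen both contrasts -> adjust ->
#' evaluate and compare, writing every artifact to `config$out_dir`:
#' `cohort.csv` (with `lr_initial,outcome,lr_final,triggering_afs` columns
#' for both panels in separate files), `screening_<label>.csv/.json`,
#' `performance.json`, `report.md` and `log.txt`. Deterministic given the
#' configuration; every artifact records the configuration hash.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory results: `cohort`,
#'   `screens`, `comparison`, `validation`, `config_hash`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
  }
  note("config-hash %s", hash)

  cohort <- if (is.null(config$csv)) {
    sample_cohort(config$spec, config$seed)
  } else {
    read_cohort_csv(config$csv)
  }
  note("stage simulate/load: %d lesions in, %d lesions out",
       nrow(cohort), nrow(cohort))

  screens <- lapply(c(all = "all", lr34 = "lr34"), function(ctr) {
    screen_panel(cohort, ctr, p_enter = config$p_enter,
                 bypass_univariable_filter = config$bypass_univariable_filter)
  })
  note("stage screen: %d lesions in, panels AF-HCC (%d AFs) / AF-LR (%d AFs)",
       nrow(cohort),
       length(screens$all$stepwise$selected),
       length(screens$lr34$stepwise$selected))

  panels <- lapply(screens, `[[`, "panel")
  adjusted <- lapply(panels, function(p) categorize_cohort(cohort, p))
  note("stage adjust: %d lesions in, %d LR-3/4 adjusted",
       nrow(cohort), sum(adjusted[[1]]$lr_initial %in% c("LR-3", "LR-4")))

  comparison <- compare_methods(cohort, panels$all, panels$lr34)
  validation <- lapply(c(all = "all", lr34 = "lr34"), function(ctr) {
    feats <- screens[[ctr]]$stepwise$selected
    if (!length(feats)) return(NULL)
    validate_model(cohort, ctr, features = feats,
                   train_fraction = config$train_fraction, seed = config$seed)
  })
  note("stage evaluate: %d LR-3/4 lesions in, reports for 2 methods out",
       comparison$report_a$n_hcc + comparison$report_a$n_nonhcc)

  paths <- write_run_artifacts(config, hash, cohort, adjusted, screens,
                               comparison, validation)
  note("stage report: artifacts %s", paste(basename(unlist(paths)),
                                           collapse = ", "))
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(list(cohort = cohort, screens = screens, comparison = comparison,
                 validation = validation, config_hash = hash, paths = paths))
}

write_run_artifacts <- function(config, hash, cohort, adjusted, screens,
                                comparison, validation) {
  out <- config$out_dir
  paths <- list(cohort = file.path(out, "cohort.csv"))
  write_cohort_csv(cohort, paths$cohort)
  for (key in names(screens)) {
    label <- screens[[key]]$label
    scr_csv <- file.path(out, sprintf("screening_%s.csv", label))
    uni <- screens[[key]]$univariable
    uni$contrast <- screens[[key]]$contrast
    uni$selected <- uni$feature %in% screens[[key]]$stepwise$selected
    uni$direction <- ifelse(
      !uni$selected, "",
      ifelse(uni$feature %in% screens[[key]]$panel$malignant_afs,
             "malignant", "benign"))
    utils::write.csv(
      cbind(uni[, c("feature", "contrast", "a", "b", "c", "d", "test",
                    "p_group", "or", "ci_low", "ci_high", "selected",
                    "direction")],
            config_hash = hash),
      scr_csv, row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, label = label,
           selected = screens[[key]]$stepwise$selected,
           malignant = screens[[key]]$panel$malignant_afs,
           benign = screens[[key]]$panel$benign_afs),
      file.path(out, sprintf("screening_%s.json", label)),
      auto_unbox = TRUE, digits = NA)
    adj_csv <- file.path(out, sprintf("cohort_adjusted_%s.csv", label))
    adj <- adjusted[[key]][, c("lesion_id", "lr_initial", "outcome",
                               "lr_final", "triggering_afs")]
    utils::write.csv(cbind(adj, config_hash = hash), adj_csv,
                     row.names = FALSE)
    paths[[paste0("screening_", label)]] <- scr_csv
    paths[[paste0("adjusted_", label)]] <- adj_csv
  }
  perf <- list(
    config_hash = hash,
    af_hcc = report_as_list(comparison$report_a),
    af_lr = report_as_list(comparison$report_b),
    kappa = comparison$kappa$kappa,
    mcnemar_sensitivity_p = comparison$mcnemar_sensitivity$p_adjusted,
    mcnemar_specificity_p = comparison$mcnemar_specificity$p_adjusted,
    validation = lapply(validation, function(v) {
      if (is.null(v)) return(NULL)
      list(train_auc = v$train_auc$auc,
           train_ci = c(v$train_auc$ci_low, v$train_auc$ci_high),
           validation_auc = v$validation_auc$auc,
           validation_ci = c(v$validation_auc$ci_low, v$validation_auc$ci_high))
    })
  )
  paths$performance <- file.path(out, "performance.json")
  jsonlite::write_json(perf, paths$performance, auto_unbox = TRUE, digits = NA)
  for (key in names(validation)) {
    v <- validation[[key]]
    if (is.null(v)) next
    label <- screens[[key]]$label
    nb <- cbind(v$net_benefit, config_hash = hash)
    cal <- cbind(v$calibration, config_hash = hash)
    paths[[paste0("net_benefit_", label)]] <-
      file.path(out, sprintf("net_benefit_%s.csv", label))
    paths[[paste0("calibration_", label)]] <-
      file.path(out, sprintf("calibration_%s.csv", label))
    utils::write.csv(nb, paths[[paste0("net_benefit_", label)]],
                     row.names = FALSE)
    utils::write.csv(cal, paths[[paste0("calibration_", label)]],
                     row.names = FALSE)
  }
  paths$report <- file.path(out, "report.md")
  writeLines(render_report(hash, screens, comparison, validation),
             paths$report)
  paths
}

report_as_list <- function(report) {
  list(outcome_counts = as.data.frame.matrix(t(report$outcome_counts)),
       sensitivity = report$sensitivity,
       specificity = report$specificity,
       n_hcc = report$n_hcc, n_nonhcc = report$n_nonhcc)
}

render_report <- function(hash, screens, comparison, validation) {
  fmt_pct <- function(x) sprintf("%.2f%%", 100 * x)
  lines <- c(
    "# LI-RADS ancillary-feature adjustment report",
    "",
    sprintf("Configuration hash: `%s`", hash),
    "",
    "## Screened panels",
    ""
  )
  for (key in names(screens)) {
    s <- screens[[key]]
    lines <- c(lines, sprintf(
      "- **%s** (contrast %s): malignant = {%s}; benign = {%s}",
      s$label, s$contrast,
      paste(s$panel$malignant_afs, collapse = ", "),
      paste(s$panel$benign_afs, collapse = ", ")))
  }
  lines <- c(lines, "", "## Diagnostic performance on LR-3/4 lesions", "")
  for (pair in list(c("AF-HCC", "report_a"), c("AF-LR", "report_b"))) {
    r <- comparison[[pair[2]]]
    lines <- c(lines, sprintf(
      "- **%s**: sensitivity %s (%d/%d), specificity %s (%d/%d)",
      pair[1], fmt_pct(r$sensitivity), r$outcome_counts["upgrade", "HCC"],
      r$n_hcc, fmt_pct(r$specificity),
      r$n_nonhcc - r$outcome_counts["upgrade", "nonHCC"], r$n_nonhcc))
  }
  lines <- c(lines, sprintf(
    "- Agreement between methods: kappa = %.3f; McNemar p (sensitivity) = %.4g, (specificity) = %.4g (Bonferroni x2)",
    comparison$kappa$kappa, comparison$mcnemar_sensitivity$p_adjusted,
    comparison$mcnemar_specificity$p_adjusted))
  lines <- c(lines, "", "## Internal 7:3 validation", "")
  for (key in names(validation)) {
    v <- validation[[key]]
    if (is.null(v)) next
    lines <- c(lines, sprintf(
      "- **%s**: train AUC %.3f (%.3f-%.3f), validation AUC %.3f (%.3f-%.3f)",
      screens[[key]]$label, v$train_auc$auc, v$train_auc$ci_low,
      v$train_auc$ci_high, v$validation_auc$auc, v$validation_auc$ci_low,
      v$validation_auc$ci_high))
  }
  lines
}
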