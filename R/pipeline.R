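# End-to-end orchestration of the two-step analysis. Each stage is a pure
# function of (artifacts on disk, config, seed): rerunning with the same
# config and seed reproduces the same files. A manifest records the config
# hash and seed of every stage.

#' Pipeline configuration
#'
#' Nested key/value configuration for the full two-step run; unspecified
#' entries keep their defaults. Print the object to see every value.
#'
#' @param ... Named overrides: `cohort` (arguments to [cohort_spec()]),
#'   `n_cycles`, `n_signal_subjects`, `classify` (list: `n_repeats`,
#'   `models`, `augmenters`, `boruta_iter`), `regress` (list: `n_repeats`,
#'   `models`, `targets`), `seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    cohort = list(),
    n_cycles = 10L,
    n_signal_subjects = 10L,
    classify = list(n_repeats = 10L, models = clf_kinds(),
                    augmenters = list(list(method = "none", target_size = "balance100"),
                                      list(method = "smote", target_size = "balance100")),
                    boruta_iter = 100L),
    regress = list(n_repeats = 10L, models = reg_kinds(),
                   targets = c("uneven_speed", "uneven_RMS_VT",
                               "uneven_SampEn_AP", "uneven_HR_AP")))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

log_stage <- function(stage, seed) {
  message(sprintf("[%s] %s (seed = %d)", format(Sys.time(), "%H:%M:%S"), stage, seed))
}

write_manifest <- function(dir, stage, cfg, extra = list()) {
  man <- c(list(stage = stage, config_hash = config_hash(cfg), seed = cfg$seed,
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time())), extra)
  jsonlite::write_json(man, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate cohort artifacts to disk
#'
#' Writes the classification feature table, the regression table (with its
#' generative ground truth), the cohort spec, and trunk/shank signal CSVs for
#' the first `n_signal_subjects` subjects.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
pipeline_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage("simulate", config$seed)
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  coh <- simulate_classification_cohort(spec)
  write_feature_csv(coh$features, file.path(out_dir, "classification_features.csv"))
  reg <- simulate_regression_cohort(spec)
  write_feature_csv(reg$features, file.path(out_dir, "regression_features.csv"))
  jsonlite::write_json(reg$truth, file.path(out_dir, "regression_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_spec_yaml(spec, file.path(out_dir, "cohort_spec.yaml"))
  n_sig <- min(config$n_signal_subjects, nrow(coh$features))
  subj <- coh$features[seq_len(n_sig), c("subject_id", "group")]
  subj$gait_time_10m <- NA_real_
  for (i in seq_len(n_sig)) {
    rec <- simulate_subject_record(subj$subject_id[i],
                                   as.character(subj$group[i]), "uneven",
                                   spec, seed = config$seed + 100L + i)
    write_signal_csv(rec$trunk_signal,
                     file.path(out_dir, paste0(rec$id, "_trunk.csv")))
    shank <- triaxial_signal(rec$shank_ap, rec$shank_ap * 0, rec$shank_ap * 0,
                             spec$fs)
    write_signal_csv(shank, file.path(out_dir, paste0(rec$id, "_shank.csv")))
    subj$gait_time_10m[i] <- rec$gait_time_10m
  }
  write_feature_csv(subj, file.path(out_dir, "subjects.csv"))
  write_manifest(out_dir, "simulate", config)
  invisible(out_dir)
}

#' Extract stability features from simulated signal files
#'
#' For every subject listed in `subjects.csv`: detect gait events on the
#' shank trace, trim 3 + 3 transient strides, extract `n_cycles` cycles from
#' the trunk signal and compute the 18 stability indicators.
#'
#' @param config A [pipeline_config()].
#' @param sim_dir Directory written by [pipeline_simulate()].
#' @param out_csv Output feature CSV (default inside `sim_dir`).
#' @return Invisibly, the feature data.frame.
#' @export
pipeline_extract <- function(config = pipeline_config(), sim_dir,
                             out_csv = file.path(sim_dir, "extracted_features.csv")) {
  log_stage("extract", config$seed)
  subj <- read_feature_csv(file.path(sim_dir, "subjects.csv"))
  rows <- lapply(seq_len(nrow(subj)), function(i) {
    id <- subj$subject_id[i]
    trunk <- read_signal_csv(file.path(sim_dir, paste0(id, "_trunk.csv")))
    shank <- read_signal_csv(file.path(sim_dir, paste0(id, "_shank.csv")))
    ev <- detect_gait_events(shank$ap, shank$fs)
    ev <- trim_transient_strides(ev)
    st <- extract_cycles(trunk, ev, n_cycles = config$n_cycles)
    sp <- gait_speed(subj$gait_time_10m[i])
    cbind(data.frame(subject_id = id, group = subj$group[i], speed = sp),
          compute_stability_features(st, sp))
  })
  out <- do.call(rbind, rows)
  write_feature_csv(out, out_csv)
  invisible(out)
}

#' Run the Step-1 classification stage
#'
#' Correlation pruning, Boruta + LASSO consensus selection, the repeated
#' augmentation-aware classifier suite, logistic odds ratios and an sPLS-DA
#' fit with per-component AUC and VIP scores. All artifacts are written to
#' `out_dir`.
#'
#' @param features Classification feature table (or path to its CSV).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list: `report`, `consensus`, `odds_ratios`, `splsda`,
#'   `vip`, `component_auc`.
#' @export
pipeline_classify <- function(features, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage("classify", config$seed)
  if (is.character(features)) features <- read_feature_csv(features)
  feat_cols <- intersect(stability_feature_names(), names(features))
  pruned <- correlation_prune(features[feat_cols])
  feat_cols <- setdiff(names(pruned$table), "group")
  pp <- preprocess_fit(features, cols = feat_cols)
  std <- preprocess_apply(pp, features)
  bor <- boruta_select(std[feat_cols], std$group,
                       n_iter = config$classify$boruta_iter, seed = config$seed)
  las <- lasso_select(std[feat_cols], std$group, seed = config$seed)
  cons <- suppressWarnings(consensus_features(bor, las))
  sel <- if (length(cons)) cons else feat_cols
  write_selection_json(bor, las, cons, file.path(out_dir, "selection.json"))
  plan <- experiment_plan(models = config$classify$models,
                          augmenters = config$classify$augmenters,
                          n_repeats = config$classify$n_repeats,
                          task = "classification")
  rep <- run_classification(features[c("group", sel)], plan)
  write_report(rep, file.path(out_dir, "classification_raw.csv"),
               file.path(out_dir, "classification_summary.json"))
  lr <- fit_model("logistic", std[sel], std$group, seed = config$seed)
  or <- odds_ratios(lr)
  utils::write.csv(data.frame(feature = names(or), odds_ratio = as.numeric(or)),
                   file.path(out_dir, "odds_ratios.csv"), row.names = FALSE)
  spl <- fit_splsda(std[sel], std$group,
                    keepX = pmin(4L, length(sel)))
  cauc <- component_auc(spl, std[sel], std$group)
  vip <- vip_scores(spl)
  write_splsda_csv(spl, out_dir)
  jsonlite::write_json(list(component_auc = as.list(cauc)),
                       file.path(out_dir, "splsda_auc.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "classify", config,
                 extra = list(consensus = as.list(sel)))
  invisible(list(report = rep, consensus = sel, odds_ratios = or,
                 splsda = spl, vip = vip, component_auc = cauc))
}

#' Run the Step-2 regression stage
#'
#' Repeated evaluation of the six-regressor suite for each uneven-surface
#' target, writing tidy raw/summary artifacts per target.
#'
#' @param features Regression feature table (or path to its CSV).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a named list of `experiment_report`s.
#' @export
pipeline_regress <- function(features, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage("regress", config$seed)
  if (is.character(features)) features <- read_feature_csv(features)
  targets <- intersect(config$regress$targets, names(features))
  plan <- experiment_plan(models = config$regress$models,
                          n_repeats = config$regress$n_repeats,
                          task = "regression")
  pred_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       config$regress$targets)
  reports <- lapply(setNames(targets, targets), function(tg) {
    r <- run_regression(features[c(pred_cols, tg)], target = tg, plan = plan)
    write_report(r, file.path(out_dir, paste0("regression_", tg, "_raw.csv")),
                 file.path(out_dir, paste0("regression_", tg, "_summary.json")))
    r
  })
  write_manifest(out_dir, "regress", config)
  invisible(reports)
}

#' Interpretation stage: PDP + Shapley + structure locators
#'
#' Fits a random forest per target on the preprocessed predictors, computes
#' partial dependence for the named features, permutation-Shapley global
#' importance, and reads off the embedded structures (speed breakpoint on the
#' uneven-speed PDP, U-shape vertex on the SampEn PDP, harmonic-ratio plateau
#' onset).
#'
#' @param features Regression feature table (or path to its CSV).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `breakpoint`, `ushape`, `plateau`,
#'   `shap_top` per relevant target.
#' @export
pipeline_interpret <- function(features, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage("interpret", config$seed)
  if (is.character(features)) features <- read_feature_csv(features)
  pred_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       config$regress$targets)
  fit_rf <- function(target) fit_model("rf", features[pred_cols],
                                       features[[target]],
                                       list(num_trees = 500), seed = config$seed)
  out <- list()
  rf_speed <- fit_rf("uneven_speed")
  pd_speed <- partial_dependence(rf_speed, features[pred_cols], "even_speed")
  out$breakpoint <- as.numeric(pdp_locate_breakpoint(
    features[c(pred_cols, "uneven_speed")], "uneven_speed", "even_speed",
    predictors = pred_cols, seed = config$seed))
  rf_se <- fit_rf("uneven_SampEn_AP")
  pd_se <- partial_dependence(rf_se, features[pred_cols], "Ang_IC_ankle")
  out$ushape <- fit_ushape(pd_se$value, pd_se$pd)
  rf_hr <- fit_rf("uneven_HR_AP")
  pd_hr <- partial_dependence(rf_hr, features[pred_cols], "even_HR_AP")
  out$plateau <- as.numeric(locate_plateau(pd_hr$value, pd_hr$pd))
  sh <- shap_values(rf_speed, features[seq_len(min(50, nrow(features))), pred_cols],
                    features[pred_cols], n_perm = 10L, seed = config$seed)
  out$shap_top <- names(sh$importance)[1L]
  write_interpretation_csv(pd_speed, sh,
                           file.path(out_dir, "pdp_even_speed.csv"),
                           file.path(out_dir, "shap_uneven_speed.csv"))
  utils::write.csv(pd_se, file.path(out_dir, "pdp_ang_ic_ankle.csv"), row.names = FALSE)
  utils::write.csv(pd_hr, file.path(out_dir, "pdp_even_hr_ap.csv"), row.names = FALSE)
  jsonlite::write_json(list(breakpoint_speed = out$breakpoint,
                            ushape_quad_coef = out$ushape$quad_coef,
                            ushape_vertex = out$ushape$vertex,
                            hr_plateau_onset = out$plateau,
                            shap_top_feature = out$shap_top),
                       file.path(out_dir, "interpretation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "interpret", config)
  invisible(out)
}

#' Collect stage artifacts into a summary report
#'
#' Reads every `*_summary.json` / `interpretation.json` under `dir` and
#' writes `report.json` plus a human-readable `report.md`; every number in
#' the summary is traceable to one of the stage artifact files.
#'
#' @param dir Directory containing pipeline outputs.
#' @return Invisibly, the summary list.
#' @export
pipeline_report <- function(dir) {
  files <- list.files(dir, pattern = "(_summary|interpretation|splsda_auc|selection)\\.json$",
                      recursive = TRUE, full.names = TRUE)
  summary <- lapply(setNames(files, basename(files)), jsonlite::read_json)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Pipeline report", "",
          sprintf("- artifacts collected: %d", length(files)),
          sprintf("  - %s", basename(files)))
  writeLines(md, file.path(dir, "report.md"))
  invisible(summary)
}
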