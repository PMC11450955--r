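# End-to-end orchestration: batch feature extraction, event-stratified
# train/test split, model fitting and full evaluation reporting.

#' Pipeline configuration
#'
#' Every default matches the method's stated settings: fat window
#' [-190, -30] HU, mRMR to 50 features, elastic-net mixing 0.8, 10 CV
#' folds, a 15-feature cap, 1,000 bootstrap iterations, a 2-year AUC/NRI
#' horizon, an 80/20 event-stratified split, and exclusion of follow-up
#' under 10 days.
#'
#' @param fat_window_lo,fat_window_hi fat window bounds (HU).
#' @param k_mrmr mRMR retention count.
#' @param alpha elastic-net mixing parameter.
#' @param nfolds CV folds.
#' @param max_features cap on the final active set.
#' @param bootstrap_iterations bootstrap iterations for validation.
#' @param auc_horizon_days AUC/NRI horizon in days (730 = 2 years).
#' @param split_fraction training fraction of the cohort.
#' @param min_followup_days records with shorter follow-up are dropped.
#' @param log_features features entered on the ln scale.
#' @param seed master RNG seed.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(fat_window_lo = -190, fat_window_hi = -30,
                            k_mrmr = 50, alpha = 0.8, nfolds = 10,
                            max_features = 15, bootstrap_iterations = 1000,
                            auc_horizon_days = 730, split_fraction = 0.8,
                            min_followup_days = 10,
                            log_features = character(), seed = 1) {
  cfg <- list(fat_window_lo = fat_window_lo, fat_window_hi = fat_window_hi,
              k_mrmr = k_mrmr, alpha = alpha, nfolds = nfolds,
              max_features = max_features,
              bootstrap_iterations = bootstrap_iterations,
              auc_horizon_days = auc_horizon_days,
              split_fraction = split_fraction,
              min_followup_days = min_followup_days,
              log_features = log_features, seed = seed)
  stopifnot(cfg$fat_window_lo < cfg$fat_window_hi, cfg$k_mrmr >= 1,
            cfg$alpha >= 0, cfg$alpha <= 1, cfg$nfolds >= 2,
            cfg$max_features >= 1, cfg$split_fraction > 0,
            cfg$split_fraction < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return \code{read_config}: a [pipeline_config()]; \code{write_config}:
#'   invisibly, \code{path}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$log_features <- as.character(vals$log_features)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Batch feature extraction over a study manifest
#'
#' The manifest lists one study per row: \code{study_id}, \code{volume}
#' (NIfTI path) and \code{sac} (NIfTI mask path).  Failures are logged per
#' study and do not abort the batch.
#'
#' @param manifest data.frame (or CSV path) with columns \code{study_id},
#'   \code{volume}, \code{sac}.
#' @param config a [pipeline_config()].
#' @param out_csv optional path; when given the feature table is written as
#'   CSV (one row per study, first column \code{study_id}).
#' @return The feature table (data.frame, 148 feature columns), with
#'   attributes \code{failures} (named character vector of error messages)
#'   and \code{n_failed}.
#' @export
run_extract <- function(manifest, config = pipeline_config(), out_csv = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("study_id", "volume", "sac")
  if (nrow(manifest) == 0) stop("run_extract: empty manifest")
  if (!all(need %in% colnames(manifest)))
    stop("run_extract: manifest needs columns ", paste(need, collapse = ", "))
  window <- fat_window(config$fat_window_lo, config$fat_window_hi)
  catalog <- feature_catalog(window)
  rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- as.character(manifest$study_id[i])
    res <- tryCatch({
      vol <- read_volume(manifest$volume[i])
      sac <- read_volume(manifest$sac[i], mask = TRUE)
      fv <- extract_features(vol, sac, window, catalog)
      as.data.frame(as.list(fv))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[sid] <- conditionMessage(res)
      message("run_extract: study ", sid, " failed: ", conditionMessage(res))
    } else {
      res <- cbind(study_id = sid, res)
      rows[[sid]] <- res
    }
  }
  if (length(rows) == 0) stop("run_extract: all studies failed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  structure(out, failures = failures, n_failed = length(failures))
}

# Event-stratified train/test split; returns logical train indicator.
stratified_split <- function(event, fraction, seed) {
  set.seed(seed)
  train <- logical(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    n_tr <- round(length(idx) * fraction)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Fit and evaluate the fat-omics model on a cohort
#'
#' Merges the feature and survival tables on \code{study_id}, drops
#' short-follow-up records, makes a seeded event-stratified train/test
#' split, runs mRMR + Cox elastic-net on the training set only, and
#' reports training, bootstrap-validation and held-out test metrics
#' (C-index, time-dependent AUC at the configured horizon, AIC, risk-score
#' hazard ratio, and median-split Kaplan-Meier stratification per subset).
#' An audit log records which study ids each stage touched; test ids never
#' appear before the evaluation stage.
#'
#' @param features feature table (data.frame or CSV path) with a
#'   \code{study_id} column.
#' @param surv survival table (data.frame or CSV path):
#'   \code{study_id}, \code{time}, \code{event}.
#' @param config a [pipeline_config()].
#' @param out_model,out_report optional JSON output paths.
#' @return List: \code{model} ([fatomics_cox()]), \code{report} (nested
#'   list of metrics), \code{split} (per-study train/test assignment),
#'   \code{audit} (stage -> study ids).
#' @export
run_fit_eval <- function(features, surv, config = pipeline_config(),
                         out_model = NULL, out_report = NULL) {
  if (is.character(features)) features <- read.csv(features, stringsAsFactors = FALSE)
  if (is.character(surv)) surv <- read.csv(surv, stringsAsFactors = FALSE)
  stopifnot("study_id" %in% colnames(features),
            all(c("study_id", "time", "event") %in% colnames(surv)))
  df <- merge(features, surv[, c("study_id", "time", "event")], by = "study_id")
  if (nrow(df) == 0) stop("run_fit_eval: no matching study_ids")
  df <- filter_followup(df, config$min_followup_days)
  feat_cols <- setdiff(colnames(features), "study_id")
  train <- stratified_split(df$event, config$split_fraction, config$seed)
  if (sum(df$event[train]) < 2 || sum(df$event[!train]) < 2)
    stop("run_fit_eval: fewer than 2 events in a split")
  audit <- list(split = df$study_id,
                mrmr = df$study_id[train], fit = df$study_id[train],
                bootstrap = df$study_id[train], evaluate = df$study_id)
  Xtr <- df[train, feat_cols, drop = FALSE]
  Xte <- df[!train, feat_cols, drop = FALSE]
  model <- fatomics_cox(Xtr, df$time[train], df$event[train],
                        k_mrmr = config$k_mrmr, alpha = config$alpha,
                        nfolds = config$nfolds,
                        max_features = config$max_features,
                        log_features = config$log_features, seed = config$seed)
  sc_tr <- predict(model, Xtr)
  sc_te <- predict(model, Xte)
  eval_subset <- function(sc, tm, ev) {
    out <- list(c_index = concordance_index(sc, tm, ev),
                auc = tryCatch(time_dependent_auc(sc, tm, ev,
                                                  config$auc_horizon_days),
                               error = function(e) NA_real_))
    km <- tryCatch(km_stratify(sc, tm, ev), error = function(e) NULL)
    if (!is.null(km))
      out <- c(out, list(logrank_p = km$logrank_p, group_hr = km$hr,
                         group_hr_ci = km$ci, km = km))
    out
  }
  train_eval <- eval_subset(sc_tr, df$time[train], df$event[train])
  test_eval <- eval_subset(sc_te, df$time[!train], df$event[!train])
  # HR of the aggregated risk score (per SD), as a single-model summary
  score_cox <- univariable_cox(sc_tr, df$time[train], df$event[train])
  sel_raw <- model$feature_names
  train_eval$aic <- tryCatch({
    Xtr_log <- apply_log_features(Xtr, model$log_features)
    cox_aic(Xtr_log, sel_raw, df$time[train], df$event[train])
  }, error = function(e) NA_real_)
  boot <- bootstrap_validate(apply_log_features(Xtr, model$log_features),
                             df$time[train], df$event[train],
                             model$feature_names,
                             iterations = config$bootstrap_iterations,
                             seed = config$seed, alpha = config$alpha,
                             nfolds = config$nfolds)
  report <- list(
    config = unclass(config),
    n = nrow(df), n_train = sum(train), n_test = sum(!train),
    event_fraction_train = mean(df$event[train]),
    event_fraction_test = mean(df$event[!train]),
    selected_features = model$feature_names,
    coefficients = as.list(model$coef),
    lambda = model$lambda,
    train = c(train_eval[c("c_index", "auc", "aic", "logrank_p", "group_hr")],
              list(score_hr_per_sd = score_cox$hr, score_hr_ci = score_cox$ci,
                   score_p = score_cox$p)),
    bootstrap = list(c_index_mean = boot$c_index$mean,
                     c_index_ci = boot$c_index$ci, skipped = boot$skipped),
    test = test_eval[c("c_index", "auc", "logrank_p", "group_hr")])
  if (!is.null(out_model)) {
    jsonlite::write_json(
      list(features = model$feature_names, coefficients = as.list(model$coef),
           alpha = model$alpha, lambda = model$lambda,
           log_features = model$log_features, seed = config$seed,
           k_mrmr = model$k_mrmr, max_features = model$max_features),
      out_model, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out_report)) {
    jsonlite::write_json(report, out_report, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  list(model = model,
       report = report,
       split = data.frame(study_id = df$study_id,
                          subset = ifelse(train, "train", "test")),
       train_scores = sc_tr, test_scores = sc_te,
       train_km = train_eval$km,
       test_km = test_eval$km,
       audit = audit)
}
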