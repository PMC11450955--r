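# Feature screening (mRMR) and the Cox elastic-net fat-omics model.

as_surv_df <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be finite and > 0")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  data.frame(time = time, event = event)
}

# |z| of a univariable Cox fit on the standardized feature; 0 for constant
# or non-informative columns.
cox_relevance <- function(x, time, event) {
  if (sd(x) == 0) return(0)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ scale(x), ties = "breslow"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ scale(x), ties = "breslow")),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(0)
  z <- coef(fit) / sqrt(diag(fit$var))
  if (!is.finite(z)) 0 else abs(z)
}

#' Maximum relevance minimum redundancy feature screening for survival data
#'
#' Greedy mRMR adapted to time-to-event outcomes: a feature's relevance is
#' the absolute z-statistic of its univariable Cox fit (on the standardized
#' feature); its redundancy is the mean absolute Pearson correlation with
#' the already-selected set.  At each step the feature maximizing
#' (relevance - redundancy) is added; ties break by column order, so the
#' selection is fully deterministic.  Zero-variance columns rank below every
#' informative feature.
#'
#' @param X data.frame or matrix of features (rows = subjects), no missing
#'   values.
#' @param time,event survival outcome (days; 1 = event).
#' @param k number of features to retain (default 50).
#' @return Character vector of \code{k} feature names in selection order.
#' @export
mrmr_select <- function(X, time, event, k = 50) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("mrmr_select: X must not contain missing values")
  surv <- as_surv_df(time, event)
  p <- ncol(X)
  if (k > p) stop("mrmr_select: k = ", k, " exceeds the ", p, " available features")
  rel <- vapply(seq_len(p), function(j) cox_relevance(X[, j], surv$time, surv$event),
                numeric(1))
  constant <- apply(X, 2, sd) == 0
  sel <- integer(0)
  avail <- seq_len(p)
  # running sum of |cor| with selected features, per candidate
  redsum <- numeric(p)
  for (step in seq_len(k)) {
    score <- if (length(sel) == 0) rel else rel - redsum / length(sel)
    score[constant] <- -Inf
    cand <- avail
    if (all(score[cand] == -Inf)) score[cand] <- rel[cand] # only constants left
    best <- cand[which.max(score[cand])]
    sel <- c(sel, best)
    avail <- setdiff(avail, best)
    if (length(avail)) {
      r <- suppressWarnings(abs(cor(X[, avail, drop = FALSE], X[, best])))
      r[!is.finite(r)] <- 0
      redsum[avail] <- redsum[avail] + as.numeric(r)
    }
  }
  colnames(X)[sel]
}

# Event-stratified, seeded CV fold assignment.
stratified_foldid <- function(event, nfolds, seed) {
  set.seed(seed)
  foldid <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Cox elastic-net fit with cross-validated penalty and a feature cap
#'
#' Maximizes the penalized Cox partial log-likelihood with penalty
#' lambda * sum(alpha*|b| + (1-alpha)*b^2/2), Breslow tie handling, via
#' glmnet.  Features are standardized internally; coefficients are reported
#' on the original scale.  lambda is chosen by cross-validated partial
#' likelihood (the lambda minimizing CV deviance); when the active set at
#' that lambda exceeds \code{max_features}, lambda is re-tightened along
#' the path (toward heavier penalty) until the active set fits the cap.
#'
#' @param X feature matrix/data.frame (rows = subjects), all finite.
#' @param time,event survival outcome; at least 2 events.
#' @param alpha elastic-net mixing parameter (default 0.8).
#' @param nfolds CV folds (default 10), event-stratified, seeded.
#' @param seed RNG seed for fold assignment.
#' @param max_features cap on the active set size (default Inf = no cap).
#' @param lambda optional fixed lambda (skips CV); a full decreasing path
#'   down to this value is fit for warm-started convergence, so
#'   \code{lambda = 0} reproduces the unpenalized Cox fit.
#' @return A \code{cox_enet} object: \code{coef} (named nonzero
#'   coefficients, original scale), \code{lambda}, \code{alpha},
#'   \code{feature_names}, the underlying \code{glmnet} fit and (when CV
#'   ran) the \code{cv} object.
#' @export
cox_enet <- function(X, time, event, alpha = 0.8, nfolds = 10, seed = 1,
                     max_features = Inf, lambda = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X)))
    stop("cox_enet: X must be numeric and finite")
  surv <- as_surv_df(time, event)
  if (sum(surv$event) < 2) stop("cox_enet: need at least 2 events")
  y <- survival::Surv(surv$time, surv$event)
  if (ncol(X) == 1L) {
    # single-feature refits are unpenalized (the penalty has nothing to trade off)
    cph <- survival::coxph(y ~ X[, 1], ties = "breslow")
    nz <- setNames(unname(coef(cph)), colnames(X))
    nz <- nz[nz != 0]
    return(structure(list(coef = nz, feature_names = names(nz), lambda = 0,
                          alpha = alpha, nfolds = nfolds, seed = seed,
                          max_features = max_features, fit = cph, cv = NULL,
                          n = nrow(X), n_events = sum(surv$event)),
                     class = "cox_enet"))
  }
  if (!is.null(lambda)) {
    stopifnot(length(lambda) == 1, lambda >= 0)
    base <- glmnet::glmnet(X, y, family = "cox", alpha = alpha)
    lmin <- max(lambda, min(base$lambda) * 1e-3)
    path <- sort(unique(c(base$lambda,
                          exp(seq(log(max(base$lambda)), log(max(lmin, 1e-10)),
                                  length.out = 60)), lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha, lambda = path,
                          thresh = 1e-12, maxit = 1e6)
    chosen <- lambda
    cv <- NULL
  } else {
    foldid <- stratified_foldid(surv$event, nfolds, seed)
    cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha, foldid = foldid)
    fit <- cv$glmnet.fit
    chosen <- cv$lambda.min
    if (is.finite(max_features)) {
      path <- fit$lambda
      i <- which.min(abs(path - chosen))
      while (i >= 1 && nnz_at(fit, path[i]) > max_features) i <- i - 1
      if (i < 1) i <- 1
      chosen <- path[i]
    }
  }
  b <- as.matrix(coef(fit, s = chosen))[, 1]
  nz <- b[b != 0]
  structure(list(coef = nz, feature_names = names(nz), lambda = chosen,
                 alpha = alpha, nfolds = nfolds, seed = seed,
                 max_features = max_features, fit = fit, cv = cv,
                 n = nrow(X), n_events = sum(surv$event)),
            class = "cox_enet")
}

nnz_at <- function(fit, s) {
  b <- as.matrix(coef(fit, s = s))[, 1]
  sum(b != 0)
}

#' @export
print.cox_enet <- function(x, ...) {
  cat("<cox_enet> alpha = ", x$alpha, ", lambda = ", signif(x$lambda, 4),
      "; ", length(x$coef), " active features (n = ", x$n, ", events = ",
      x$n_events, ")\n", sep = "")
  invisible(x)
}

#' Fit the fat-omics Cox survival model
#'
#' The package's central model: maximum relevance minimum redundancy
#' screening of the feature table down to \code{k_mrmr} features, followed
#' by a Cox proportional-hazards elastic-net fit (mixing parameter
#' \code{alpha}, \code{nfolds}-fold cross-validated penalty, Breslow ties)
#' whose active set is capped at \code{max_features} by re-tightening the
#' penalty along the path.  The fitted risk score is the linear predictor
#' sum(coef_j * x_j) over the selected features.
#'
#' @param X data.frame or matrix of features (rows = subjects; typically
#'   the 148-column fat-omics table), no missing values.
#' @param time,event survival outcome (days; 1 = event).
#' @param k_mrmr number of features retained by mRMR screening (default 50).
#' @param alpha elastic-net mixing parameter (default 0.8).
#' @param nfolds CV folds for the penalty (default 10).
#' @param max_features cap on the final active set (default 15).
#' @param log_features names of features entered on the natural-log scale
#'   (e.g. \code{"EAT_vol"}); applied before screening and fitting, and
#'   again by \code{predict}.
#' @param seed RNG seed (CV fold assignment).
#' @return A \code{fatomics_cox} object with \code{print}, \code{summary},
#'   \code{coef} and \code{predict} methods.
#' @seealso [mrmr_select()], [cox_enet()], [risk_score()]
#' @export
fatomics_cox <- function(X, time, event, k_mrmr = 50, alpha = 0.8, nfolds = 10,
                         max_features = 15, log_features = character(),
                         seed = 1) {
  X <- as.data.frame(X)
  surv <- as_surv_df(time, event)
  if (nrow(X) != nrow(surv)) stop("fatomics_cox: X rows must match outcome length")
  X <- apply_log_features(X, log_features)
  k_mrmr <- min(k_mrmr, ncol(X))
  keep <- mrmr_select(X, surv$time, surv$event, k = k_mrmr)
  enet <- cox_enet(X[, keep, drop = FALSE], surv$time, surv$event, alpha = alpha,
                   nfolds = nfolds, seed = seed, max_features = max_features)
  scores <- as.numeric(as.matrix(X[, enet$feature_names, drop = FALSE]) %*% enet$coef)
  structure(list(coef = enet$coef, feature_names = enet$feature_names,
                 lambda = enet$lambda, alpha = alpha, nfolds = nfolds,
                 k_mrmr = k_mrmr, max_features = max_features,
                 mrmr_features = keep, log_features = log_features,
                 seed = seed, enet = enet, n = nrow(X),
                 n_events = sum(surv$event),
                 train_c_index = concordance_index(scores, surv$time, surv$event),
                 call = match.call()),
            class = "fatomics_cox")
}

apply_log_features <- function(X, log_features) {
  for (f in log_features) {
    if (!f %in% colnames(X)) stop("log feature not in table: ", f)
    if (any(X[[f]] <= 0)) stop("log feature must be positive: ", f)
    X[[f]] <- log(X[[f]])
    colnames(X)[colnames(X) == f] <- paste0("Ln_", f)
  }
  X
}

#' @export
print.fatomics_cox <- function(x, ...) {
  cat("Fat-omics Cox elastic-net model\n")
  cat("  n = ", x$n, " subjects, ", x$n_events, " events\n", sep = "")
  cat("  mRMR screening: ", x$k_mrmr, " features; active set: ",
      length(x$coef), " (cap ", x$max_features, ")\n", sep = "")
  cat("  alpha = ", x$alpha, ", lambda = ", signif(x$lambda, 4),
      ", training C-index = ", round(x$train_c_index, 3), "\n", sep = "")
  invisible(x)
}

#' @export
coef.fatomics_cox <- function(object, ...) object$coef

#' @export
summary.fatomics_cox <- function(object, ...) {
  tab <- data.frame(feature = object$feature_names,
                    coefficient = as.numeric(object$coef),
                    hr_per_unit = exp(as.numeric(object$coef)))
  structure(list(coefficients = tab, n = object$n, n_events = object$n_events,
                 alpha = object$alpha, lambda = object$lambda,
                 train_c_index = object$train_c_index),
            class = "summary.fatomics_cox")
}

#' @export
print.summary.fatomics_cox <- function(x, ...) {
  cat("Fat-omics Cox elastic-net model (n = ", x$n, ", events = ", x$n_events,
      ")\nalpha = ", x$alpha, ", lambda = ", signif(x$lambda, 4),
      ", training C-index = ", round(x$train_c_index, 3), "\n\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
predict.fatomics_cox <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  raw_names <- sub("^Ln_", "", object$feature_names)
  need_log <- intersect(object$log_features, raw_names)
  missing <- setdiff(ifelse(raw_names %in% object$log_features, raw_names,
                            object$feature_names), colnames(newdata))
  if (length(missing))
    stop("predict.fatomics_cox: missing feature(s): ", paste(missing, collapse = ", "))
  newdata <- apply_log_features(newdata, need_log)
  as.numeric(as.matrix(newdata[, object$feature_names, drop = FALSE]) %*% object$coef)
}

#' Linear fat-omics risk score
#'
#' The risk score is the sum of each selected feature multiplied by its
#' coefficient (features registered as log-features enter on the ln scale).
#'
#' @param model a [fatomics_cox()] (or \code{cox_enet}) model.
#' @param newdata data.frame containing every selected feature.
#' @return Numeric vector of per-subject scores.
#' @export
risk_score <- function(model, newdata) {
  if (inherits(model, "fatomics_cox")) return(predict(model, newdata))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$feature_names, colnames(newdata))
  if (length(missing))
    stop("risk_score: missing feature(s): ", paste(missing, collapse = ", "))
  as.numeric(as.matrix(newdata[, model$feature_names, drop = FALSE]) %*% model$coef)
}

#' Univariable Cox analysis of a single feature
#'
#' Unpenalized Cox fit on the standardized feature (so the hazard ratio is
#' per SD), with Wald confidence interval and p-value, Harrell's C-index of
#' the fitted predictor, and AIC = -2 logPL + 2.
#'
#' @param x numeric feature with positive variance.
#' @param time,event survival outcome.
#' @param conf_level CI level (default 0.95).
#' @return List: \code{beta}, \code{se}, \code{hr}, \code{ci} (length 2),
#'   \code{p}, \code{c_index}, \code{aic}.
#' @export
univariable_cox <- function(x, time, event, conf_level = 0.95) {
  if (sd(x) == 0) stop("univariable_cox: feature has zero variance")
  surv <- as_surv_df(time, event)
  z <- as.numeric(scale(x))
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ z, ties = "breslow")
  beta <- unname(coef(fit))
  se <- sqrt(diag(fit$var))
  q <- qnorm(1 - (1 - conf_level) / 2)
  list(beta = beta, se = se, hr = exp(beta),
       ci = exp(beta + c(-1, 1) * q * se),
       p = 2 * pnorm(-abs(beta / se)),
       c_index = concordance_index(beta * z, surv$time, surv$event),
       aic = -2 * fit$loglik[2] + 2)
}
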