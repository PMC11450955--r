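# Time-to-event model evaluation: Harrell's C, IPCW time-dependent AUC,
# AIC, Kaplan-Meier risk stratification, bootstrap validation, categorical
# net reclassification improvement.

#' Harrell's concordance index
#'
#' Over comparable pairs (i, j) with t_i < t_j and event_i = 1, the fraction
#' for which score_i > score_j, score ties counted 0.5.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param time,event survival outcome.
#' @return Scalar C-index in [0, 1].
#' @export
concordance_index <- function(scores, time, event) {
  surv <- as_surv_df(time, event)
  scores <- as.numeric(scores)
  if (length(scores) != nrow(surv)) stop("concordance_index: length mismatch")
  num <- 0; den <- 0
  for (i in which(surv$event == 1L)) {
    comp <- surv$time > surv$time[i]
    n_comp <- sum(comp)
    if (n_comp == 0) next
    den <- den + n_comp
    num <- num + sum(scores[i] > scores[comp]) + 0.5 * sum(scores[i] == scores[comp])
  }
  if (den == 0) stop("concordance_index: no comparable pairs")
  num / den
}

# Kaplan-Meier of the censoring distribution, returned as a left-continuous
# step function G(t-) suitable for IPCW weights.
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  # G(t-): probability of remaining uncensored just before t
  function(t, minus = FALSE) {
    tt <- if (minus) t - 1e-9 else t
    idx <- findInterval(tt, fit$time)
    ifelse(idx == 0, 1, fit$surv[pmax(idx, 1)])
  }
}

#' IPCW time-dependent AUC (cumulative/dynamic)
#'
#' Cases are subjects with an observed event by the horizon; controls are
#' subjects event-free past it.  Censoring before the horizon is handled by
#' inverse-probability-of-censoring weights from the Kaplan-Meier estimate
#' of the censoring distribution: cases weigh 1/G(T_i-), controls 1/G(t).
#' With no censoring this reduces to the plain binary AUC of
#' (event by t) vs score.
#'
#' @param scores numeric risk scores.
#' @param time,event survival outcome (days).
#' @param horizon_days evaluation horizon in days (default 730 = 2 years).
#' @return Scalar AUC.
#' @export
time_dependent_auc <- function(scores, time, event, horizon_days = 730) {
  surv <- as_surv_df(time, event)
  scores <- as.numeric(scores)
  t0 <- horizon_days
  case <- surv$time <= t0 & surv$event == 1L
  ctrl <- surv$time > t0
  if (!any(case) || !any(ctrl))
    stop("time_dependent_auc: need both cases and controls at the horizon")
  G <- censoring_km(surv$time, surv$event)
  w_case <- 1 / G(surv$time[case], minus = TRUE)
  w_ctrl <- rep(1 / G(t0), sum(ctrl))
  if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl)))
    stop("time_dependent_auc: censoring weights degenerate at the horizon")
  sc <- scores[case]; st <- scores[ctrl]
  num <- 0
  for (i in seq_along(sc)) {
    num <- num + w_case[i] * sum(w_ctrl * ((sc[i] > st) + 0.5 * (sc[i] == st)))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' AIC of an unpenalized Cox refit on a fixed feature set
#'
#' The selected features are refit without penalty (Breslow ties) and
#' AIC = -2 logPL + 2k is reported, k the number of features; k = 0 gives
#' the null-model AIC.
#'
#' @param X feature table.
#' @param features character vector of selected feature names (possibly
#'   empty).
#' @param time,event survival outcome.
#' @return Scalar AIC.
#' @export
cox_aic <- function(X, features, time, event) {
  surv <- as_surv_df(time, event)
  if (length(features) == 0) {
    fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ 1, ties = "breslow")
    return(-2 * fit$loglik[1])
  }
  X <- as.data.frame(X)
  missing <- setdiff(features, colnames(X))
  if (length(missing)) stop("cox_aic: missing feature(s): ", paste(missing, collapse = ", "))
  df <- X[, features, drop = FALSE]
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ .,
                         data = df, ties = "breslow")
  if (any(is.na(coef(fit)))) stop("cox_aic: refit did not converge (NA coefficients)")
  -2 * fit$loglik[2] + 2 * length(features)
}

#' Kaplan-Meier risk stratification at the median score
#'
#' Subjects are split into high risk (score > median) and low risk
#' (score <= median); per-group product-limit survival curves, the
#' two-sample log-rank test, and the between-group hazard ratio from a
#' univariable Cox fit on the group indicator are returned.
#'
#' @param scores numeric risk scores (n >= 4, not all tied at the median).
#' @param time,event survival outcome.
#' @return List: \code{curves} (data.frame per group: time, survival,
#'   at-risk), \code{logrank_p}, \code{hr}, \code{ci}, \code{groups}
#'   (factor high/low per subject).
#' @export
km_stratify <- function(scores, time, event) {
  surv <- as_surv_df(time, event)
  scores <- as.numeric(scores)
  if (length(scores) < 4) stop("km_stratify: need n >= 4")
  med <- median(scores)
  high <- scores > med
  if (!any(high) || all(high))
    stop("km_stratify: all subjects on one side of the median (tied scores)")
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  sv <- survival::Surv(surv$time, surv$event)
  fit <- survival::survfit(sv ~ grp)
  sd <- survival::survdiff(sv ~ grp)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(sv ~ grp, ties = "breslow")
  beta <- unname(coef(cx)); se <- sqrt(diag(cx$var))
  strata <- rep(names(fit$strata), fit$strata)
  curves <- split(data.frame(time = fit$time, survival = fit$surv,
                             at_risk = fit$n.risk), strata)
  names(curves) <- sub("^grp=", "", names(curves))
  curves <- curves[c("low", "high")]
  list(curves = curves, logrank_p = p, hr = exp(beta),
       ci = exp(beta + c(-1, 1) * qnorm(0.975) * se), groups = grp)
}

#' Bootstrap validation of a fixed-feature Cox model
#'
#' For each iteration, subjects are resampled with replacement, the
#' fixed-feature Cox elastic-net model is refit on the resample (penalty by
#' cross-validation), and the C-index (plus, optionally, the time-dependent
#' AUC) is evaluated on the out-of-bag subjects.  Iterations whose
#' out-of-bag set lacks events are skipped and counted.  Fully seeded.
#'
#' @param X feature table.
#' @param time,event survival outcome.
#' @param features fixed feature names to refit.
#' @param iterations bootstrap iterations (>= 2; 1,000 for a full run).
#' @param seed RNG seed.
#' @param alpha,nfolds elastic-net settings for the refits.
#' @param auc_horizon_days if non-NULL, also evaluate the IPCW AUC at this
#'   horizon.
#' @return List: per metric \code{mean}, \code{ci} (percentile 2.5/97.5),
#'   \code{values}; plus \code{skipped} (count) and \code{iterations}.
#' @export
bootstrap_validate <- function(X, time, event, features, iterations = 1000,
                               seed = 1, alpha = 0.8, nfolds = 10,
                               auc_horizon_days = NULL) {
  if (iterations < 2) stop("bootstrap_validate: need >= 2 iterations")
  X <- as.data.frame(X)
  surv <- as_surv_df(time, event)
  n <- nrow(surv)
  Xf <- as.matrix(X[, features, drop = FALSE])
  set.seed(seed)
  cvals <- rep(NA_real_, iterations)
  avals <- rep(NA_real_, iterations)
  skipped <- 0L
  for (b in seq_len(iterations)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) < 2 || sum(surv$event[oob]) == 0 || sum(surv$event[idx]) < 2) {
      skipped <- skipped + 1L
      next
    }
    fit <- tryCatch(
      cox_enet(Xf[idx, , drop = FALSE], surv$time[idx], surv$event[idx],
               alpha = alpha, nfolds = nfolds, seed = seed + b),
      error = function(e) NULL)
    if (is.null(fit) || length(fit$coef) == 0) { skipped <- skipped + 1L; next }
    sc <- as.numeric(Xf[oob, fit$feature_names, drop = FALSE] %*% fit$coef)
    cvals[b] <- tryCatch(concordance_index(sc, surv$time[oob], surv$event[oob]),
                         error = function(e) NA_real_)
    if (!is.null(auc_horizon_days))
      avals[b] <- tryCatch(
        time_dependent_auc(sc, surv$time[oob], surv$event[oob], auc_horizon_days),
        error = function(e) NA_real_)
  }
  summarize <- function(v) {
    v <- v[!is.na(v)]
    list(mean = mean(v), ci = unname(quantile(v, c(0.025, 0.975))), values = v)
  }
  out <- list(c_index = summarize(cvals), skipped = skipped, iterations = iterations)
  if (!is.null(auc_horizon_days)) out$auc <- summarize(avals)
  out
}

#' Categorical net reclassification improvement at a horizon
#'
#' Subjects are categorized high/low by each model's own median score; event
#' status at the horizon is established with IPCW weighting (events before
#' the horizon weigh 1/G(T-), event-free subjects 1/G(t); subjects censored
#' before the horizon drop out and the weights compensate).  Components:
#' NRI_event = P(up | event) - P(down | event), NRI_nonevent =
#' P(down | nonevent) - P(up | nonevent), overall = their sum.
#'
#' @param scores_new,scores_ref risk scores of the new and reference models
#'   on the same subjects.
#' @param time,event survival outcome.
#' @param horizon_days evaluation horizon (default 730).
#' @return List: \code{overall}, \code{event}, \code{nonevent}.
#' @export
categorical_nri <- function(scores_new, scores_ref, time, event,
                            horizon_days = 730) {
  surv <- as_surv_df(time, event)
  scores_new <- as.numeric(scores_new); scores_ref <- as.numeric(scores_ref)
  if (length(scores_new) != nrow(surv) || length(scores_ref) != nrow(surv))
    stop("categorical_nri: score/outcome length mismatch")
  if (horizon_days > max(surv$time))
    stop("categorical_nri: horizon beyond observed follow-up")
  hi_new <- scores_new > median(scores_new)
  hi_ref <- scores_ref > median(scores_ref)
  up <- hi_new & !hi_ref
  down <- !hi_new & hi_ref
  is_event <- surv$time <= horizon_days & surv$event == 1L
  is_nonevent <- surv$time > horizon_days
  G <- censoring_km(surv$time, surv$event)
  w <- numeric(nrow(surv))
  w[is_event] <- 1 / G(surv$time[is_event], minus = TRUE)
  w[is_nonevent] <- 1 / G(horizon_days)
  if (sum(w[is_event]) == 0 || sum(w[is_nonevent]) == 0)
    stop("categorical_nri: no events or no nonevents at the horizon")
  nri_event <- (sum(w[is_event & up]) - sum(w[is_event & down])) / sum(w[is_event])
  nri_nonevent <- (sum(w[is_nonevent & down]) - sum(w[is_nonevent & up])) /
    sum(w[is_nonevent])
  list(overall = nri_event + nri_nonevent, event = nri_event,
       nonevent = nri_nonevent)
}
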