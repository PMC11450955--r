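# Independent hand-trace of the greedy criterion: relevance = |z| of the
# univariable Cox fit, redundancy = mean |cor| with the selected set, pick
# argmax(relevance - redundancy) at each step.
trace_mrmr <- function(X, time, event, k) {
  rel <- apply(X, 2, function(x) {
    uc <- suppressWarnings(univariable_cox(x, time, event))
    abs(uc$beta / uc$se)
  })
  sel <- character(0)
  while (length(sel) < k) {
    cand <- setdiff(colnames(X), sel)
    score <- vapply(cand, function(f) {
      red <- if (length(sel) == 0) 0 else mean(abs(cor(X[, f], X[, sel])))
      rel[f] - red
    }, numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

test_that("mRMR screening follows the greedy relevance-redundancy trade-off", {
  for (seed in c(15, 16, 17)) {
    set.seed(seed)
    n <- 150
    top <- rnorm(n)
    other <- 0.15 * top + rnorm(n)
    lp <- 0.35 * top + 0.25 * other
    T <- rexp(n, exp(lp)); C <- rexp(n, 0.25)
    time <- pmin(T, C); event <- as.integer(T <= C)
    X <- cbind(top = top, top_copy = top, other = other)
    expect_identical(mrmr_select(X, time, event, k = 3),
                     trace_mrmr(X, time, event, 3))
  }

  # a configuration where the redundancy penalty defers the exact duplicate
  # below the weakly correlated informative feature
  set.seed(4)
  n <- 150
  top <- rnorm(n)
  other <- 0.15 * top + rnorm(n)
  lp <- 0.35 * top + 0.25 * other
  T <- rexp(n, exp(lp)); C <- rexp(n, 0.25)
  time <- pmin(T, C); event <- as.integer(T <= C)
  X <- cbind(top = top, top_copy = top, other = other)
  sel <- mrmr_select(X, time, event, k = 3)
  expect_identical(sel, c("top", "other", "top_copy"))
  expect_identical(sel, trace_mrmr(X, time, event, 3))

  # exhaustive k returns all columns; determinism; k > p errors
  expect_setequal(sel, colnames(X))
  expect_identical(sel, mrmr_select(X, time, event, k = 3))
  expect_error(mrmr_select(X, time, event, k = 5), "exceeds")

  # constant column never precedes informative ones
  X2 <- cbind(X, flat = rep(1, n))
  sel2 <- mrmr_select(X2, time, event, k = 4)
  expect_equal(sel2[4], "flat")
})

test_that("elastic net at zero penalty reproduces the unpenalized Cox fit", {
  d <- sim_cox_data(200, beta = c(1, -1), censor_rate = 0.3, seed = 7)
  fit0 <- cox_enet(d$X, d$time, d$event, alpha = 0.8, lambda = 0)
  cph <- survival::coxph(survival::Surv(d$time, d$event) ~ d$X, ties = "breslow")
  expect_equal(unname(fit0$coef), unname(coef(cph)), tolerance = 1e-4)
})

test_that("heavy penalty shrinks every coefficient to zero", {
  d <- sim_cox_data(150, beta = c(1, -1), seed = 8)
  fit <- cox_enet(d$X, d$time, d$event, alpha = 0.8, lambda = 50)
  expect_length(fit$coef, 0)
})

test_that("the active set is non-increasing along the penalty path", {
  d <- sim_cox_data(300, beta = c(1, -0.8, 0.5, rep(0, 7)), seed = 9)
  fit <- cox_enet(d$X, d$time, d$event, alpha = 0.8, seed = 2)
  nz <- fit$fit$df # glmnet's active-set count, lambda decreasing
  expect_true(all(diff(nz) >= 0))
})

test_that("rescaling a feature column leaves the risk-score ordering unchanged", {
  d <- sim_cox_data(200, beta = c(1, -1, 0.5), censor_rate = 0.3, seed = 10)
  f1 <- cox_enet(d$X, d$time, d$event, alpha = 0.8, seed = 5)
  X2 <- d$X
  X2[, 1] <- X2[, 1] * 1000
  f2 <- cox_enet(X2, d$time, d$event, alpha = 0.8, seed = 5)
  s1 <- as.numeric(d$X[, f1$feature_names, drop = FALSE] %*% f1$coef)
  s2 <- as.numeric(X2[, f2$feature_names, drop = FALSE] %*% f2$coef)
  expect_identical(order(s1), order(s2))
})

test_that("fatomics_cox screens to 50 and caps the active set at 15", {
  X <- simulate_cohort_features(300, seed = 41)
  sv <- simulate_survival(X, cohort_spec(300, default_signal_beta(),
                                         event_fraction = 0.56, seed = 42))
  m <- fatomics_cox(X, sv$time, sv$event, seed = 3)
  expect_length(m$mrmr_features, 50L)
  expect_lte(length(coef(m)), 15L)
  expect_gt(length(coef(m)), 0L)
  expect_s3_class(m, "fatomics_cox")
  expect_output(print(m), "active set")
  expect_output(print(summary(m)), "coefficient")

  # prediction contract
  expect_error(predict(m, X[, 1:3]), "missing feature")
  sc <- predict(m, X)
  expect_length(sc, 300)
  expect_true(all(is.finite(sc)))
  # risk score is the plain linear combination
  expect_equal(sc, as.numeric(as.matrix(X[, m$feature_names]) %*% m$coef))
})

test_that("risk scores are linear and respond monotonically to features", {
  toy <- structure(list(coef = c(a = 2), feature_names = "a"), class = "cox_enet")
  expect_equal(risk_score(toy, data.frame(a = 3)), 6)
  expect_equal(risk_score(toy, data.frame(a = 0)), 0)
  expect_error(risk_score(toy, data.frame(b = 1)), "missing")
  # increasing a positive-coefficient feature strictly increases the score
  expect_gt(risk_score(toy, data.frame(a = 4)), risk_score(toy, data.frame(a = 3)))
})

test_that("log-registered features enter the model on the ln scale", {
  set.seed(30)
  n <- 200
  X <- data.frame(EAT_vol = exp(rnorm(n, 4, 0.5)), other = rnorm(n))
  lp <- 1.2 * scale(log(X$EAT_vol))[, 1]
  T <- rexp(n, exp(lp))
  m <- fatomics_cox(X, T, rep(1L, n), k_mrmr = 2, max_features = 2,
                    log_features = "EAT_vol", seed = 1)
  expect_true(any(grepl("^Ln_EAT_vol$", m$mrmr_features)))
  sc <- predict(m, X)
  if ("Ln_EAT_vol" %in% m$feature_names) {
    expect_equal(sc, as.numeric(log(X$EAT_vol) * m$coef[["Ln_EAT_vol"]] +
      if ("other" %in% m$feature_names) X$other * m$coef[["other"]] else 0))
  }
})

test_that("univariable Cox recovers simulated effects and ranks perfectly", {
  # perfect concordance when the score reproduces the event-time ranking
  set.seed(18)
  t <- sort(rexp(50)); e <- rep(1L, 50)
  uc <- suppressWarnings(univariable_cox(-t, t, e)) # monotone likelihood
  expect_equal(uc$c_index, 1.0)

  # consistency: beta = 0.5 per SD at n = 2000, ~30% censoring
  d <- sim_cox_data(2000, beta = 0.5, censor_rate = 0.4, seed = 19)
  uc2 <- univariable_cox(d$X[, 1], d$time, d$event)
  expect_lt(abs(log(uc2$hr) - 0.5), 0.1)
  expect_error(univariable_cox(rep(2, 10), rexp(10), rep(1L, 10)), "variance")
})

test_that("univariable Cox confidence intervals show nominal null coverage", {
  nseed <- 150
  covered <- logical(nseed)
  for (s in seq_len(nseed)) {
    d <- sim_cox_data(400, beta = 0, censor_rate = 0.3, seed = 1000 + s)
    uc <- univariable_cox(d$X[, 1], d$time, d$event)
    covered[s] <- uc$ci[1] <= 1 && 1 <= uc$ci[2]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
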