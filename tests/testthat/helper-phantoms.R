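# Shared phantom constructors for tests (small grids, fast to build).

# Spherical sac of radius r_mm with an EAT shell of thickness t_mm, isotropic
# voxels of h_mm.
shell_phantom <- function(r_mm = 25, t_mm = 8, h_mm = 1, hu_sd = 0, seed = 1,
                          hu_mean = -80) {
  n <- ceiling(2 * (r_mm + 4) / h_mm)
  phantom_spec(dim = c(n, n, n), spacing = rep(h_mm, 3),
               semiaxes = rep(r_mm, 3),
               thickness = list(type = "constant", t0 = t_mm),
               hu_eat = list(type = "gaussian", mean = hu_mean, sd = hu_sd),
               seed = seed)
}

# The default anisotropic ellipsoidal phantom at test scale.
small_ellipsoid_phantom <- function(seed = 1, ...) {
  args <- list(dim = c(24, 48, 48), spacing = c(2.5, 1.5, 1.5),
               semiaxes = c(22, 30, 28), seed = seed)
  dots <- list(...)
  if (!"thickness" %in% names(dots))
    args$thickness <- list(type = "constant", t0 = 8)
  do.call(phantom_spec, c(args, dots))
}

# Quick standard survival simulation on q features with given true betas.
sim_cox_data <- function(n, beta, censor_rate = 0.3, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lp <- as.numeric(X %*% beta)
  T <- rexp(n, rate = exp(lp))
  C <- if (censor_rate > 0) rexp(n, rate = censor_rate * mean(exp(lp))) else rep(Inf, n)
  list(X = X, time = pmin(T, C), event = as.integer(T <= C), lp = lp)
}
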