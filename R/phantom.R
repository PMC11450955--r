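# Synthetic CT phantoms and survival cohorts: every pipeline stage gets an
# input with analytic or generative ground truth.

#' Phantom specification
#'
#' Describes an ellipsoidal pericardial sac carrying an EAT shell of
#' controllable thickness field and HU distribution, voxelized on an
#' anisotropic grid.  The default grid (40 slices of 128 x 128 at
#' 2.5 x 1 x 1 mm) is a scaled-down version of a clinical calcium-score
#' acquisition (~50 slices of 512 x 512 at 2.5 x 0.5 x 0.5 mm); use
#' \code{phantom_spec_clinical()} for the full-size preset.
#'
#' @param dim grid shape (nz, ny, nx).
#' @param spacing voxel spacing (dz, dy, dx) mm.
#' @param semiaxes sac ellipsoid semi-axes (az, ay, ax) mm.
#' @param center sac centre (z, y, x) mm; default grid centre.
#' @param thickness EAT thickness field t(phi, theta) in mm:
#'   \code{list(type = "constant", t0)},
#'   \code{list(type = "gradient", t0, a)} for t0 + a*cos(phi) (thicker at
#'   the top of the heart), or \code{list(type = "lobed", t0, a)} for
#'   t0 + a*cos(theta)*sin(phi).
#' @param hu_eat EAT HU model: \code{list(type = "gaussian", mean, sd)},
#'   \code{list(type = "skewnormal", location, scale, shape)}, or
#'   \code{list(type = "binmix", probs)} with 8 probabilities over the
#'   canonical 20-HU window bins (uniform within each bin).
#' @param hu_core HU of the non-fat sac interior (default +40, myocardium-like).
#' @param hu_background HU outside the sac (default -900, lung-like).
#' @param noise_sd SD of additive Gaussian noise applied to every voxel.
#' @param seed RNG seed for HU sampling.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(dim = c(40, 128, 128), spacing = c(2.5, 1, 1),
                         semiaxes = c(38, 55, 50), center = NULL,
                         thickness = list(type = "constant", t0 = 10),
                         hu_eat = list(type = "gaussian", mean = -80, sd = 20),
                         hu_core = 40, hu_background = -900,
                         noise_sd = 0, seed = 1) {
  dim <- as.integer(dim)
  if (is.null(center)) center <- (dim - 1) * spacing / 2
  stopifnot(length(dim) == 3, all(dim >= 2), all(spacing > 0),
            length(semiaxes) == 3, all(semiaxes > 0),
            all(is.finite(center)), is.list(thickness), is.list(hu_eat))
  if (is.null(thickness$a)) thickness$a <- 0
  if (thickness$t0 < 0 || thickness$t0 - abs(thickness$a) < 0)
    stop("phantom_spec: thickness field must be >= 0 everywhere")
  # shell must sit strictly inside the grid
  extent <- (dim - 1) * spacing
  if (any(center - semiaxes < 0) || any(center + semiaxes > extent))
    stop("phantom_spec: sac ellipsoid must lie strictly inside the grid")
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 semiaxes = as.numeric(semiaxes), center = as.numeric(center),
                 thickness = thickness, hu_eat = hu_eat, hu_core = hu_core,
                 hu_background = hu_background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Clinical-geometry phantom preset
#' @param ... overrides passed to [phantom_spec()].
#' @return A \code{phantom_spec} at 50 slices of 512 x 512, 2.5 x 0.5 x 0.5 mm.
#' @export
phantom_spec_clinical <- function(...) {
  phantom_spec(dim = c(50, 512, 512), spacing = c(2.5, 0.5, 0.5),
               semiaxes = c(50, 70, 65), ...)
}

# Skew-normal sampler via the delta representation:
# Z = delta*|U0| + sqrt(1-delta^2)*U1, delta = shape/sqrt(1+shape^2).
rskewnormal <- function(n, location = 0, scale = 1, shape = 0) {
  delta <- shape / sqrt(1 + shape^2)
  u0 <- rnorm(n); u1 <- rnorm(n)
  location + scale * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

sample_eat_hu <- function(n, model, window = fat_window()) {
  switch(model$type,
    gaussian = rnorm(n, model$mean, model$sd),
    skewnormal = rskewnormal(n, model$location, model$scale, model$shape),
    binmix = {
      probs <- model$probs
      if (length(probs) != 8 || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
        stop("binmix HU model: probs must be 8 nonnegative values summing to 1")
      edges <- hu_bin_edges(window, 8L)
      bin <- sample.int(8L, n, replace = TRUE, prob = probs)
      runif(n, edges[bin], edges[bin + 1])
    },
    stop("unknown EAT HU model type: ", model$type))
}

#' Generate a synthetic CT phantom
#'
#' Voxelizes the sac ellipsoid; the EAT shell consists of sac voxels whose
#' inward signed distance to the ellipsoid surface (exact for spheres,
#' first-order otherwise) is at most t(phi, theta), the thickness field
#' evaluated at the voxel's direction from the sac centre.
#' HU values are assigned by region (background / core / EAT model), then
#' optional Gaussian noise is added.  Fully seeded: identical specs give
#' identical phantoms.
#'
#' @param spec a [phantom_spec()].
#' @return List with \code{volume} ([image_volume()]), \code{sac}
#'   ([binary_mask()]), \code{eat} (the constructed shell, [binary_mask()])
#'   and \code{truth}: voxel counts and mm^3 volumes of sac and EAT, the
#'   analytic shell volume when the sac is spherical with constant
#'   thickness, the thickness and HU parameters, and a \code{thin_shell}
#'   flag raised when the requested shell is thinner than one voxel.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dim; sp <- spec$spacing; ce <- spec$center; ax <- spec$semiaxes
  z <- (0:(d[1] - 1)) * sp[1] - ce[1]
  y <- (0:(d[2] - 1)) * sp[2] - ce[2]
  x <- (0:(d[3] - 1)) * sp[3] - ce[3]
  Z <- array(z, d)
  Y <- array(rep(y, each = d[1]), d)
  X <- array(rep(x, each = d[1] * d[2]), d)
  f <- sqrt((Z / ax[1])^2 + (Y / ax[2])^2 + (X / ax[3])^2)
  sac <- f <= 1
  # inward distance to the ellipsoid surface, first-order: (1 - f) / |grad f|
  # (exact for spheres; avoids the half-voxel bias of a discrete transform)
  gf <- sqrt((Z / ax[1]^2)^2 + (Y / ax[2]^2)^2 + (X / ax[3]^2)^2) / pmax(f, 1e-12)
  dist <- ifelse(f > 1e-12, (1 - f) / gf, min(ax))
  r <- sqrt(Z^2 + Y^2 + X^2)
  phi <- acos(pmin(1, pmax(-1, ifelse(r > 0, Z / r, 1))))
  theta <- atan2(Y, X)
  t0 <- spec$thickness$t0; a <- spec$thickness$a
  tfield <- switch(spec$thickness$type,
    constant = array(t0, d),
    gradient = t0 + a * cos(phi),
    lobed = t0 + a * cos(theta) * sin(phi),
    stop("unknown thickness field type: ", spec$thickness$type))
  eat <- sac & (dist <= tfield)
  hu <- array(spec$hu_background, d)
  hu[sac] <- spec$hu_core
  hu[eat] <- sample_eat_hu(sum(eat), spec$hu_eat)
  if (spec$noise_sd > 0) hu <- hu + rnorm(length(hu), 0, spec$noise_sd)
  vv <- prod(sp)
  spherical <- max(ax) - min(ax) < 1e-9 && spec$thickness$type == "constant"
  truth <- list(
    sac_voxels = sum(sac), sac_volume_mm3 = sum(sac) * vv,
    eat_voxels = sum(eat), eat_volume_mm3 = sum(eat) * vv,
    eat_volume_analytic_mm3 = if (spherical)
      4 / 3 * pi * (ax[1]^3 - max(0, ax[1] - t0)^3) else NA_real_,
    sac_volume_analytic_mm3 = 4 / 3 * pi * prod(ax),
    thickness = spec$thickness, hu_eat = spec$hu_eat,
    thin_shell = !any(eat) || min(tfield[eat]) < max(sp))
  if (truth$thin_shell)
    truth$warning <- "EAT shell thinner than one voxel in places"
  list(volume = image_volume(hu, sp), sac = binary_mask(sac, sp),
       eat = binary_mask(eat, sp), truth = truth)
}

#' Cohort specification for survival simulation
#'
#' @param n number of subjects (>= 2).
#' @param beta named vector of generative Cox coefficients (per SD of the
#'   named features).
#' @param weibull_shape,weibull_scale baseline Weibull hazard parameters
#'   (time in days).  Defaults give a median event time of roughly 1.5
#'   years for an average-risk subject.
#' @param event_fraction target fraction of subjects with an observed event,
#'   in (0, 1]; 1 disables censoring.  The MACE-enriched default is 0.56.
#' @param admin_days administrative censoring window (default 6 years =
#'   2190 days): censoring times are uniform on (0, c_max] with
#'   c_max <= admin_days calibrated to the target event fraction.
#' @param seed RNG seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n, beta, weibull_shape = 1.2, weibull_scale = 800,
                        event_fraction = 0.56, admin_days = 2190, seed = 1) {
  stopifnot(n >= 2, length(beta) >= 1, !is.null(names(beta)),
            weibull_shape > 0, weibull_scale > 0,
            event_fraction > 0, event_fraction <= 1, admin_days > 0)
  structure(list(n = as.integer(n), beta = beta, weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale, event_fraction = event_fraction,
                 admin_days = admin_days, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate survival records from a feature table
#'
#' Event times follow a Weibull proportional-hazards model: with linear
#' predictor lp = sum(beta_j * z_ij) over standardized features z,
#' T = scale * (-log(U) / exp(lp))^(1/shape).  Censoring times are uniform
#' on (0, c_max], with c_max <= the administrative window calibrated so the
#' realized event fraction hits the target within +/- 5 percent; an
#' unattainable target raises an error stating the achievable range.
#'
#' @param features data.frame or matrix of features (rows = subjects)
#'   containing every name in \code{spec$beta}.
#' @param spec a [cohort_spec()] with \code{spec$n == nrow(features)}.
#' @return data.frame \code{(study_id, time, event)}, time in days, event
#'   1 = observed, 0 = censored; the linear predictor is attached as
#'   attribute \code{"lp"}.
#' @export
simulate_survival <- function(features, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  features <- as.data.frame(features)
  missing <- setdiff(names(spec$beta), colnames(features))
  if (length(missing))
    stop("simulate_survival: features missing from table: ",
         paste(missing, collapse = ", "))
  if (nrow(features) != spec$n)
    stop("simulate_survival: feature table has ", nrow(features),
         " rows but spec$n = ", spec$n)
  set.seed(spec$seed)
  Z <- scale(as.matrix(features[, names(spec$beta), drop = FALSE]))
  Z[is.nan(Z)] <- 0 # constant columns contribute nothing
  lp <- as.numeric(Z %*% spec$beta)
  u <- runif(spec$n)
  T <- spec$weibull_scale * (-log(u) / exp(lp))^(1 / spec$weibull_shape)
  if (spec$event_fraction >= 1) {
    time <- T; event <- rep(1L, spec$n)
  } else {
    # P(event_i | c_max) = P(C >= T_i) with C ~ U(0, c_max)
    pfrac <- function(cmax) mean(pmax(0, 1 - T / cmax))
    pmax_att <- pfrac(spec$admin_days)
    if (spec$event_fraction > pmax_att + 0.05)
      stop("simulate_survival: target event fraction ", spec$event_fraction,
           " unattainable; achievable range is (0, ", round(pmax_att, 3),
           "] under the ", spec$admin_days, "-day window")
    cmax <- if (spec$event_fraction >= pmax_att) spec$admin_days else
      uniroot(function(cm) pfrac(cm) - spec$event_fraction,
              lower = min(T) / 2 + 1e-9, upper = spec$admin_days)$root
    C <- runif(spec$n, 0, cmax)
    time <- pmin(T, C)
    event <- as.integer(T <= C)
  }
  out <- data.frame(study_id = sprintf("S%04d", seq_len(spec$n)),
                    time = time, event = event)
  attr(out, "lp") <- lp
  out
}

#' Drop records with very short follow-up
#'
#' Cohort-cleaning rule: records with follow-up below \code{min_days}
#' (default 10) are excluded.
#'
#' @param surv data.frame with columns \code{time}, \code{event}.
#' @param min_days minimum follow-up in days.
#' @return The filtered data.frame.
#' @export
filter_followup <- function(surv, min_days = 10) {
  surv[surv$time >= min_days, , drop = FALSE]
}

#' Simulate a correlated fat-omics feature table
#'
#' A statistical emulation of a cohort feature table carrying the 148
#' catalog names: features load on a small number of latent factors (so
#' blocks of features are correlated, as real morphology/HU/thickness
#' features are) plus independent noise.  Values are standardized-scale
#' surrogates for modeling experiments, not extracted measurements.
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param n_factors number of latent factors.
#' @param noise_sd residual SD relative to unit factor variance.
#' @return data.frame, \code{n} rows x 148 catalog-named columns.
#' @export
simulate_cohort_features <- function(n, seed = 1, n_factors = 12, noise_sd = 0.6) {
  cat <- feature_catalog()
  set.seed(seed)
  p <- nrow(cat)
  load <- matrix(rnorm(p * n_factors, 0, 0.5), p, n_factors)
  fac <- matrix(rnorm(n * n_factors), n, n_factors)
  X <- fac %*% t(load) + matrix(rnorm(n * p, 0, noise_sd), n, p)
  colnames(X) <- cat$name
  as.data.frame(X)
}

#' A strong 15-feature generative signal
#'
#' Named coefficient vector over 15 catalog features echoing the high-risk
#' fat-omics themes (upper-bin HU volume, negative HU skewness, thickness
#' kurtosis, top-slab volume, overall volume), for use with
#' [simulate_survival()] in modeling experiments.
#'
#' @return Named numeric vector of 15 coefficients.
#' @export
default_signal_beta <- function() {
  c(vol_50_30 = 0.45, Negative_skewness = 0.40, Thickness_Kurtosis = 0.35,
    Vol_PQ4 = 0.40, EAT_vol = 0.30, Pro_50_30 = 0.35, vol_70_50 = 0.30,
    Thickness_Max = 0.25, Major_Axis = 0.25, HUmean_Shell1 = -0.30,
    EAT_HUmean = 0.25, Vol_PQ2 = 0.20, Thickness_SD = 0.20,
    vol_50_30_PQ4 = 0.30, Pro_190_170 = -0.25)
}
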