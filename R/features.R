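# Fat-omics feature extraction: morphology, HU statistics, HU histogram
# bins, ray-cast thickness, and per-subregion (slab/shell) features.

# Population moments.  Skewness is Fisher g1 = m3/m2^1.5; kurtosis is
# non-excess m4/m2^2 (Gaussian -> 3).  Degenerate (zero-variance) samples
# get skewness 0 and kurtosis 0 so feature vectors stay finite.
moments_stats <- function(v) {
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 <= 0) return(list(mean = mu, sd = 0, skew = 0, kurt = 0))
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  list(mean = mu, sd = sqrt(m2), skew = m3 / m2^1.5, kurt = m4 / m2^2)
}

hu_bin_edges <- function(window, n_bins) {
  seq(window$lo, window$hi, length.out = n_bins + 1L)
}

hu_bin_suffix <- function(window, n_bins) {
  e <- round(abs(hu_bin_edges(window, n_bins)))
  paste0(e[-length(e)], "_", e[-1])
}

# Bin membership over the window; last bin closed on the right.
hu_bin_counts <- function(hu, window, n_bins) {
  edges <- hu_bin_edges(window, n_bins)
  inside <- hu >= window$lo & hu <= window$hi
  idx <- findInterval(hu[inside], edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = n_bins)
}

#' Morphologic features of the sac and EAT masks
#'
#' Volumes in cm^3 (voxel count times physical voxel volume), the EAT/sac
#' volume fraction, and the sac's principal axis lengths.  Axis lengths use
#' the 4*sqrt(lambda) convention on the eigenvalues of the physical-coordinate
#' covariance of sac voxel centres (major >= intermediate >= minor, mm);
#' aspect ratio is major/minor.
#'
#' @param sac,eat non-empty [binary_mask()]s on the same grid.
#' @return Named numeric vector: \code{EAT_vol}, \code{SAC_vol},
#'   \code{EAT_frac}, \code{Major_Axis}, \code{Intermediate_Axis},
#'   \code{Minor_Axis}, \code{Aspect_Ratio}.
#' @export
morphology_features <- function(sac, eat) {
  stop_if_mismatch(sac, eat, "sac and eat masks")
  if (!any(sac$data)) stop("morphology_features: empty sac mask")
  vv <- voxel_volume(sac)
  sac_vol <- sum(sac$data) * vv / 1000 # mm^3 -> cm^3
  eat_vol <- sum(eat$data) * vv / 1000
  ax <- principal_axes(sac)
  if (ax[3] <= 0) warning("morphology_features: degenerate (coplanar) sac mask; minor axis 0")
  c(EAT_vol = eat_vol, SAC_vol = sac_vol,
    EAT_frac = if (sac_vol > 0) eat_vol / sac_vol else 0,
    Major_Axis = ax[1], Intermediate_Axis = ax[2], Minor_Axis = ax[3],
    Aspect_Ratio = if (ax[3] > 0) ax[1] / ax[3] else Inf)
}

# Principal axis lengths (mm) of a mask: 4*sqrt(eigenvalues) of the
# population covariance of voxel-centre physical coordinates.
principal_axes <- function(mask) {
  xyz <- mask_coords(mask)
  n <- nrow(xyz)
  mu <- colMeans(xyz)
  cc <- sweep(xyz, 2, mu)
  cov <- crossprod(cc) / n
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  4 * sqrt(ev)
}

# Physical (z,y,x) -> returned as columns (z, y, x) in mm for mask voxels.
mask_coords <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE) # (z, y, x), 1-based
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# Physical centroid of a mask, (z, y, x) mm.
mask_centroid <- function(mask) colMeans(mask_coords(mask))

#' HU distribution statistics over a masked region
#'
#' Mean, min, max, standard deviation (population), Fisher skewness g1,
#' non-excess kurtosis (Gaussian -> 3), and \code{Negative_skewness = -g1}.
#' Elevated EAT HU (a fat-inflammation correlate) shifts mass toward the
#' upper window bins and makes \code{Negative_skewness} more positive.
#'
#' @param vol an [image_volume()].
#' @param mask a [binary_mask()] with at least 3 foreground voxels.
#' @param prefix name prefix for the returned entries (default "EAT_HU").
#' @return Named numeric vector of 7 statistics.
#' @export
hu_statistics <- function(vol, mask, prefix = "EAT_HU") {
  stop_if_mismatch(vol, mask)
  hu <- vol$data[mask$data]
  if (length(hu) < 3) stop("hu_statistics: need >= 3 masked voxels for moments")
  st <- moments_stats(hu)
  setNames(c(st$mean, min(hu), max(hu), st$sd, st$skew, -st$skew, st$kurt),
           c(paste0(prefix, c("mean", "min", "max", "sd", "skewness")),
             "Negative_skewness", paste0(prefix, "kurtosis")))
}

#' HU histogram bin features
#'
#' The fat window is split into \code{n_bins} equal-width bins (8 bins of
#' 20 HU or 4 bins of 40 HU over the default window).  Per bin, the absolute
#' volume in cm^3 (\code{vol_A_B}, A/B the absolute HU bounds) and the
#' normalized probability (\code{Pro_A_B}); probabilities sum to 1 over the
#' window.
#'
#' @param vol an [image_volume()].
#' @param mask a non-empty [binary_mask()].
#' @param n_bins 4 or 8.
#' @param window a [fat_window()].
#' @param suffix appended to feature names (used for subregions).
#' @return Named numeric vector of \code{2 * n_bins} entries.
#' @export
hu_histogram_features <- function(vol, mask, n_bins = 8, window = fat_window(),
                                  suffix = "") {
  stop_if_mismatch(vol, mask)
  if (!n_bins %in% c(4L, 8L)) stop("hu_histogram_features: n_bins must be 4 or 8")
  counts <- hu_bin_counts(vol$data[mask$data], window, n_bins)
  vols <- counts * voxel_volume(vol) / 1000
  total <- sum(counts)
  pro <- if (total > 0) counts / total else rep(NA_real_, n_bins)
  nm <- hu_bin_suffix(window, n_bins)
  setNames(c(vols, pro), paste0(c(paste0("vol_", nm), paste0("Pro_", nm)), suffix))
}

#' Ray-cast EAT thickness map
#'
#' From the physical centroid of the sac, rays are cast on a 1-degree grid
#' (polar angle 0..179 deg from +z, azimuth 0..359 deg in the xy-plane) and
#' marched outward in steps of \code{min(spacing)/2} mm until past the sac's
#' bounding sphere.  A sample is "in fat" when its containing voxel lies in
#' the EAT mask; each ray's thickness is the Euclidean distance between its
#' first and last in-fat sample.  Rays meeting no fat contribute 0, so the
#' map always holds 180 x 360 = 64,800 measurements.
#'
#' @param eat EAT [binary_mask()] (subset of the sac).
#' @param sac pericardial-sac [binary_mask()], non-empty.
#' @return A \code{thickness_map}: 180 x 360 numeric matrix (rows = polar
#'   angle, cols = azimuth) with attributes \code{origin_point} (centroid,
#'   (z,y,x) mm) and \code{step} (mm).
#' @export
thickness_map <- function(eat, sac) {
  stop_if_mismatch(eat, sac, "eat and sac masks")
  if (!any(sac$data)) stop("thickness_map: empty sac mask")
  if (any(eat$data & !sac$data)) stop("thickness_map: eat mask must be inside the sac")
  if (!any(eat$data)) warning("thickness_map: empty EAT mask; all thicknesses are 0")
  centroid <- mask_centroid(sac) # (z, y, x) mm
  step <- min(sac$spacing) / 2
  rmax <- if (any(sac$data)) {
    xyz <- mask_coords(sac)
    sqrt(max(rowSums(sweep(xyz, 2, centroid)^2))) + step
  } else step
  m <- cpp_raycast(as.logical(eat$data), dim(eat$data), eat$spacing, eat$origin,
                   centroid, step, rmax)
  structure(m, origin_point = centroid, step = step, class = c("thickness_map", "matrix"))
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- as.numeric(x)
  cat("<thickness_map> 180 x 360 (", length(v), " rays); mean ",
      signif(mean(v), 4), " mm, max ", signif(max(v), 4), " mm; ",
      sum(v == 0), " rays without fat\n", sep = "")
  invisible(x)
}

#' Statistical features of the thickness distribution
#'
#' Mean, max, SD, median, skewness and kurtosis over all 64,800 ray
#' thicknesses, plus 4 fixed 8-mm histogram bins ([0,8), [8,16), [16,24),
#' [24,32] mm) reported both as absolute ray counts and as fractions of the
#' 64,800 rays.
#'
#' @param tm a [thickness_map()].
#' @return Named numeric vector of 14 entries (\code{Thickness_*}).
#' @export
thickness_features <- function(tm) {
  v <- as.numeric(tm)
  if (length(v) != 64800L) stop("thickness_features: expected 64,800 entries")
  st <- moments_stats(v)
  edges <- c(0, 8, 16, 24, 32)
  counts <- vapply(1:4, function(i) {
    if (i < 4) sum(v >= edges[i] & v < edges[i + 1])
    else sum(v >= edges[i] & v <= edges[i + 1])
  }, numeric(1))
  nm <- paste0(edges[-5], "_", edges[-1])
  c(Thickness_Mean = st$mean, Thickness_Max = max(v), Thickness_SD = st$sd,
    Thickness_Median = median(v), Thickness_Skewness = st$skew,
    Thickness_Kurtosis = st$kurt,
    setNames(counts, paste0("Thickness_N_", nm)),
    setNames(counts / length(v), paste0("Thickness_Frac_", nm)))
}

# Per-subregion feature block: EAT volume, HU mean/SD/skewness, and the 8
# HU-bin volumes, computed on EAT intersected with the subregion.  Empty
# intersections yield zeros (common for inner shells when fat hugs the sac
# boundary).
subregion_features <- function(vol, eat, region, label, window) {
  inter <- eat$data & region$data
  nm12 <- c(paste0(c("Vol_", "HUmean_", "HUsd_", "HUskew_"), label),
            paste0("vol_", hu_bin_suffix(window, 8L), "_", label))
  if (!any(inter)) return(setNames(numeric(12), nm12))
  hu <- vol$data[inter]
  st <- moments_stats(hu)
  counts <- hu_bin_counts(hu, window, 8L)
  setNames(c(sum(inter) * voxel_volume(vol) / 1000, st$mean, st$sd, st$skew,
             counts * voxel_volume(vol) / 1000), nm12)
}

#' The fat-omics feature catalog
#'
#' Registry of the 148 feature definitions: 7 morphologic + 7 HU statistics
#' + 24 HU histogram (8 bins and 4 bins, volumes and probabilities) + 14
#' thickness = 52 global features, plus 12 features (volume, HU mean/SD/
#' skewness, 8 HU-bin volumes) for each of the 8 subregions (axial slabs
#' PQ1..PQ4, radial shells Shell1..Shell4) = 96.
#'
#' @param window a [fat_window()].
#' @return A data.frame with columns \code{name}, \code{category}
#'   (morphologic/HU/spatial/thickness), \code{subregion} ("" for global),
#'   of exactly 148 rows; class \code{feature_catalog}.
#' @export
feature_catalog <- function(window = fat_window()) {
  b8 <- hu_bin_suffix(window, 8L)
  b4 <- hu_bin_suffix(window, 4L)
  tb <- c("0_8", "8_16", "16_24", "24_32")
  global <- rbind(
    data.frame(name = c("EAT_vol", "SAC_vol", "EAT_frac", "Major_Axis",
                        "Intermediate_Axis", "Minor_Axis", "Aspect_Ratio"),
               category = "morphologic"),
    data.frame(name = c("EAT_HUmean", "EAT_HUmin", "EAT_HUmax", "EAT_HUsd",
                        "EAT_HUskewness", "Negative_skewness", "EAT_HUkurtosis"),
               category = "HU"),
    data.frame(name = c(paste0("vol_", b8), paste0("Pro_", b8),
                        paste0("vol_", b4), paste0("Pro_", b4)),
               category = "HU"),
    data.frame(name = c("Thickness_Mean", "Thickness_Max", "Thickness_SD",
                        "Thickness_Median", "Thickness_Skewness", "Thickness_Kurtosis",
                        paste0("Thickness_N_", tb), paste0("Thickness_Frac_", tb)),
               category = "thickness"))
  global$subregion <- ""
  regions <- c(paste0("PQ", 1:4), paste0("Shell", 1:4))
  sub <- do.call(rbind, lapply(regions, function(r)
    data.frame(name = c(paste0(c("Vol_", "HUmean_", "HUsd_", "HUskew_"), r),
                        paste0("vol_", b8, "_", r)),
               category = "spatial", subregion = r)))
  cat <- rbind(global, sub)
  stopifnot(nrow(cat) == 148L, !anyDuplicated(cat$name))
  attr(cat, "window") <- window
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}

#' Extract the full 148-entry fat-omics feature vector
#'
#' Orchestrates the whole per-study extraction: per-slice 3x3 median
#' filtering, fat-window thresholding inside the sac, axial slab and radial
#' shell construction (shell width from the sac's major principal axis
#' length / 8), and all global and per-subregion feature operators.  HU
#' features are computed on the filtered volume.
#'
#' @param vol an [image_volume()] (raw HU).
#' @param sac pericardial-sac [binary_mask()].
#' @param window a [fat_window()].
#' @param catalog a [feature_catalog()]; extraction asserts the output names
#'   match it exactly.
#' @return Named numeric vector of length 148, in catalog order, with the
#'   EAT mask, subregions and thickness map attached as attributes
#'   (\code{"eat"}, \code{"slabs"}, \code{"shells"}, \code{"thickness_map"}).
#' @export
extract_features <- function(vol, sac, window = fat_window(),
                             catalog = feature_catalog(window)) {
  filt <- median_filter_slices(vol)
  eat <- eat_mask(filt, sac, window, prefiltered = TRUE)
  morph <- morphology_features(sac, eat)
  slabs <- axial_slabs(sac)
  shells <- radial_shells(sac, morph[["Major_Axis"]])
  if (sum(eat$data) >= 3) {
    hustat <- hu_statistics(filt, eat)
  } else {
    warning("extract_features: fewer than 3 EAT voxels; HU statistics set to 0")
    hustat <- setNames(numeric(7), c("EAT_HUmean", "EAT_HUmin", "EAT_HUmax",
                                     "EAT_HUsd", "EAT_HUskewness",
                                     "Negative_skewness", "EAT_HUkurtosis"))
  }
  hist8 <- hu_histogram_features(filt, eat, 8L, window)
  hist4 <- hu_histogram_features(filt, eat, 4L, window)
  tm <- thickness_map(eat, sac)
  thick <- thickness_features(tm)
  sub <- c(
    unlist(lapply(seq_along(slabs$masks), function(i)
      subregion_features(filt, eat, slabs$masks[[i]], slabs$labels[i], window))),
    unlist(lapply(seq_along(shells$masks), function(i)
      subregion_features(filt, eat, shells$masks[[i]], shells$labels[i], window))))
  fv <- c(morph, hustat, hist8, hist4, thick, sub)
  fv <- fv[catalog$name] # enforce catalog order
  if (anyNA(names(fv)) || !identical(names(fv), catalog$name))
    stop("extract_features: computed features do not match the catalog")
  structure(fv, eat = eat, slabs = slabs, shells = shells, thickness_map = tm)
}
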