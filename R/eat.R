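#' Fat attenuation window
#'
#' The HU interval regarded as adipose tissue.  The default [-190, -30] HU
#' is the standard EAT window; the 8 canonical 20-HU histogram bins
#' (vol_190_170 .. vol_50_30) tile exactly this interval.
#'
#' @param lo,hi window bounds in HU, \code{lo < hi}.
#' @return A \code{fat_window} object.
#' @export
fat_window <- function(lo = -190, hi = -30) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("fat_window: need finite lo < hi")
  structure(list(lo = lo, hi = hi), class = "fat_window")
}

#' Per-slice 3x3 median filter
#'
#' Noise reduction prior to fat thresholding: each axial slice is filtered
#' independently with a 3x3 median kernel (border values replicated).
#'
#' @param vol an [image_volume()].
#' @return A filtered [image_volume()] with unchanged shape, spacing, origin.
#' @export
median_filter_slices <- function(vol) {
  if (!inherits(vol, "image_volume")) stop("median_filter_slices: need an image_volume")
  out <- cpp_median3x3(as.numeric(vol$data), dim(vol$data))
  image_volume(array(out, dim(vol$data)), vol$spacing, vol$origin)
}

#' Derive the EAT mask from a pericardial-sac mask
#'
#' EAT voxels are sac voxels whose (median-filtered) HU falls inside the fat
#' window, inclusive on both bounds.
#'
#' @param vol an [image_volume()] (raw HU; filtered internally unless
#'   \code{prefiltered = TRUE}).
#' @param sac pericardial-sac [binary_mask()] on the same grid.
#' @param window a [fat_window()].
#' @param prefiltered set TRUE if \code{vol} is already median-filtered.
#' @return A [binary_mask()] of EAT voxels.  An empty result is allowed and
#'   raises a warning.
#' @export
eat_mask <- function(vol, sac, window = fat_window(), prefiltered = FALSE) {
  if (!inherits(vol, "image_volume")) stop("eat_mask: need an image_volume")
  if (!inherits(sac, "binary_mask")) stop("eat_mask: need a binary_mask")
  stop_if_mismatch(vol, sac)
  if (!prefiltered) vol <- median_filter_slices(vol)
  m <- sac$data & (vol$data >= window$lo) & (vol$data <= window$hi)
  if (!any(m)) warning("eat_mask: no sac voxel falls inside the fat window")
  binary_mask(m, vol$spacing, vol$origin)
}

#' Split a mask into 4 equally thick axial slabs (PQ1..PQ4)
#'
#' The contiguous range of slices containing any foreground voxel is split
#' into 4 consecutive blocks of (near-)equal slice count; remainder slices
#' go to the bottom-most slabs first, so block sizes differ by at most 1.
#' PQ1 is the bottom of the heart (lowest slice indices), PQ4 the top.
#'
#' @param parent a non-empty [binary_mask()] occupying at least 4 slices.
#' @return A \code{subregion_set}: labels PQ1..PQ4, one mask per label,
#'   pairwise disjoint, union equal to the parent.
#' @export
axial_slabs <- function(parent) {
  if (!inherits(parent, "binary_mask")) stop("axial_slabs: need a binary_mask")
  occ <- which(apply(parent$data, 1, any))
  if (length(occ) == 0) stop("axial_slabs: empty parent mask")
  z_lo <- min(occ); z_hi <- max(occ)
  n <- z_hi - z_lo + 1L
  if (n < 4L) stop("axial_slabs: parent occupies ", n, " slices; need >= 4")
  sizes <- rep(n %/% 4L, 4L)
  rem <- n %% 4L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- z_lo - 1L + cumsum(sizes)
  starts <- c(z_lo, ends[-4] + 1L)
  masks <- vector("list", 4L)
  for (i in 1:4) {
    m <- array(FALSE, dim(parent$data))
    zz <- starts[i]:ends[i]
    m[zz, , ] <- parent$data[zz, , , drop = FALSE]
    masks[[i]] <- binary_mask(m, parent$spacing, parent$origin)
  }
  subregion_set(paste0("PQ", 1:4), masks, parent)
}

#' Split a sac mask into 4 equidistant radial shells
#'
#' Shell width is \code{major_axis_len / 8} mm.  Shells are successive
#' boundary layers produced by physical-distance erosion (anisotropy-aware
#' Euclidean distance transform thresholding): Shell_i contains voxels whose
#' distance to the mask exterior lies in ((i-1)w, i*w] for i = 1..3, and
#' Shell4 is the remaining core (distance > 3w).  Shell1 is the outermost.
#'
#' @param sac a non-empty [binary_mask()] not touching the grid border.
#' @param major_axis_len length scale in mm (> 0); typically the sac's major
#'   principal axis length.
#' @return A \code{subregion_set}: labels Shell1..Shell4.  An empty core is
#'   allowed and raises a warning.
#' @export
radial_shells <- function(sac, major_axis_len) {
  if (!inherits(sac, "binary_mask")) stop("radial_shells: need a binary_mask")
  if (!any(sac$data)) stop("radial_shells: empty sac mask")
  if (!is.finite(major_axis_len) || major_axis_len <= 0)
    stop("radial_shells: major_axis_len must be > 0")
  w <- major_axis_len / 8
  d <- sqrt(cpp_edt_sq(as.logical(sac$data), dim(sac$data), sac$spacing))
  d <- array(d, dim(sac$data))
  masks <- vector("list", 4L)
  for (i in 1:3) {
    m <- sac$data & (d > (i - 1) * w) & (d <= i * w)
    masks[[i]] <- binary_mask(m, sac$spacing, sac$origin)
  }
  core <- sac$data & (d > 3 * w)
  if (!any(core)) warning("radial_shells: erosion emptied the mask; Shell4 (core) is empty")
  masks[[4]] <- binary_mask(core, sac$spacing, sac$origin)
  subregion_set(paste0("Shell", 1:4), masks, sac)
}

subregion_set <- function(labels, masks, parent) {
  stopifnot(length(labels) == length(masks))
  structure(list(labels = labels, masks = setNames(masks, labels), parent = parent),
            class = "subregion_set")
}

#' @export
print.subregion_set <- function(x, ...) {
  counts <- vapply(x$masks, function(m) sum(m$data), numeric(1))
  cat("<subregion_set> ", paste(x$labels, collapse = ", "),
      " (", paste(counts, collapse = "/"), " voxels; parent ",
      sum(x$parent$data), ")\n", sep = "")
  invisible(x)
}

#' Write a subregion set as a single integer-labelled NIfTI
#'
#' Background 0, subregions 1..4 in label order.
#'
#' @param x a \code{subregion_set}.
#' @param path output NIfTI path.
#' @return Invisibly, \code{path}.
#' @export
write_subregion_labels <- function(x, path) {
  lab <- array(0, dim(x$parent$data))
  for (i in seq_along(x$masks)) lab[x$masks[[i]]$data] <- i
  write_volume(image_volume(lab, x$parent$spacing, x$parent$origin), path)
}
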