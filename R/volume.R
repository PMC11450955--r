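#' CT image volume container
#'
#' A 3D Hounsfield-unit grid with physical voxel spacing, in index order
#' (slice, row, col) = (z, y, x).  All geometric operations in the package
#' work in physical millimetres; the physical position of voxel
#' (i, j, k) (0-based) is \code{origin + c(i, j, k) * spacing}, i.e.
#' coordinates are voxel-centre based.  "Top of the heart" is the highest
#' slice index.
#'
#' @param data numeric 3D array, HU values, dim (nz, ny, nx), all finite.
#' @param spacing numeric length-3 vector (dz, dy, dx) in mm, all positive.
#' @param origin numeric length-3 vector (z0, y0, x0) in mm.
#' @return An object of class \code{image_volume} with elements
#'   \code{data}, \code{spacing}, \code{origin}.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- validate_grid(data, "image_volume")
  if (!all(is.finite(data))) stop("image_volume: data must be finite")
  list_vol(data, spacing, origin, "image_volume")
}

#' Binary mask companion to an image volume
#'
#' Same shape/spacing conventions as [image_volume()]; stores a logical grid.
#'
#' @param data logical (or coercible 0/1 numeric) 3D array, dim (nz, ny, nx).
#' @inheritParams image_volume
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- validate_grid(data, "binary_mask")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("binary_mask: data must not contain NA")
  list_vol(data, spacing, origin, "binary_mask")
}

validate_grid <- function(data, what) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop(what, ": data must be a 3D array, got ",
         if (is.array(data)) paste0(length(dim(data)), "D") else class(data)[1])
  if (any(dim(data) < 2L))
    stop(what, ": each dimension must be >= 2")
  data
}

list_vol <- function(data, spacing, origin, class) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop(class, ": spacing must be 3 positive finite numbers (dz, dy, dx)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop(class, ": origin must be 3 finite numbers (z0, y0, x0)")
  structure(list(data = data, spacing = spacing, origin = origin), class = class)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels (z,y,x); spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; HU range [", signif(min(x$data), 5), ", ", signif(max(x$data), 5), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels (z,y,x); spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; ", sum(x$data), " foreground voxels\n", sep = "")
  invisible(x)
}

stop_if_mismatch <- function(a, b, what = "volume and mask") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, " must share the same grid shape: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(what, " must share the same voxel spacing")
  invisible(TRUE)
}

#' Voxel volume in mm^3
#' @param x an [image_volume()] or [binary_mask()].
#' @return Scalar, product of the three spacings.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Read a NIfTI volume or mask
#'
#' Reads a NIfTI-1 file (.nii or .nii.gz) into an [image_volume()] (default)
#' or [binary_mask()].  Voxel spacing is taken from the NIfTI pixdim; the
#' origin from the translation column of the stored affine.  NIfTI stores
#' grids in (x, y, z) fastest-to-slowest order; they are transposed into the
#' package's (z, y, x) convention.
#'
#' @param path path to an existing NIfTI file.
#' @param mask logical; if TRUE return a [binary_mask()] (nonzero voxels).
#' @return An [image_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected a 3D image, got ", length(dim(arr)), "D: ", path)
  sp_xyz <- abs(RNifti::pixdim(img))[1:3]
  aff <- RNifti::xform(img)
  orig_xyz <- as.numeric(aff[1:3, 4])
  data <- aperm(arr, c(3, 2, 1)) # (x,y,z) -> (z,y,x)
  spacing <- rev(sp_xyz)
  origin <- rev(orig_xyz)
  if (mask) binary_mask(data != 0, spacing, origin)
  else image_volume(data, spacing, origin)
}

#' Write a volume or mask as NIfTI
#'
#' Writes NIfTI-1 with the spacing encoded in pixdim and the origin in the
#' affine translation.  Masks are written as 8-bit integers in {0, 1}; HU
#' volumes as 32-bit floats.
#'
#' @param vol an [image_volume()] or [binary_mask()].
#' @param path output path ending in .nii or .nii.gz; parent must exist.
#' @return Invisibly, \code{path}.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("write_volume: parent directory does not exist: ", dirname(path))
  is_mask <- inherits(vol, "binary_mask")
  if (!is_mask && !inherits(vol, "image_volume"))
    stop("write_volume: need an image_volume or binary_mask")
  arr <- aperm(vol$data, c(3, 2, 1)) # (z,y,x) -> (x,y,z)
  if (is_mask) storage.mode(arr) <- "integer"
  sp_xyz <- rev(vol$spacing)
  orig_xyz <- rev(vol$origin)
  aff <- diag(4)
  aff[1, 1] <- sp_xyz[1]; aff[2, 2] <- sp_xyz[2]; aff[3, 3] <- sp_xyz[3]
  aff[1:3, 4] <- orig_xyz
  attr(arr, "pixdim") <- sp_xyz
  img <- RNifti::asNifti(arr, datatype = if (is_mask) "uint8" else "float")
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
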