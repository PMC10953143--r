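#' 3D intensity volume
#'
#' Container for a scalar image on a regular 3D grid: the voxel values, the
#' voxel spacing in millimetres and the declared intensity bounds.  All
#' image-valued functions in the package accept and return `volume3d`
#' objects (plain 3D arrays are promoted with spacing 1 mm).
#'
#' @param values numeric 3D array of finite voxel intensities.
#' @param voxel_size_mm positive voxel edge length(s) in mm; either a single
#'   value for isotropic grids or one value per axis.
#' @param intensity_range declared `(min, max)` intensity bounds, default
#'   `c(0, 1)` for min-max rescaled images.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(runif(8^3), dim = c(8, 8, 8)))
#' dim(v$values)
#' @export
volume3d <- function(values, voxel_size_mm = 1, intensity_range = c(0, 1)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume contains non-finite values")
  if (!length(voxel_size_mm) %in% c(1L, 3L) || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 1 or 3 positive values")
  structure(
    list(values = values,
         voxel_size_mm = as.numeric(voxel_size_mm),
         intensity_range = as.numeric(intensity_range)),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size_mm, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

as_volume3d <- function(x, voxel_size_mm = 1) {
  if (is_volume3d(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(volume3d(x, voxel_size_mm))
  stop("cannot interpret input as a 3D volume")
}

# Extract the numeric array from a volume3d or pass a bare array through.
vol_values <- function(x) if (is_volume3d(x)) x$values else x

vol_spacing <- function(x) if (is_volume3d(x)) x$voxel_size_mm else 1

#' Read and write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} that map between NIfTI-1 files and
#' [volume3d()] objects.  The voxel spacing is taken from / written to the
#' NIfTI `pixdim` field; values round-trip at single float precision or
#' better.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` returns a [volume3d()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  vals <- as.array(img)
  if (length(dim(vals)) == 4L && dim(vals)[4L] == 1L)
    vals <- array(vals, dim = dim(vals)[1:3])
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI image: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (max(sp) - min(sp) < 1e-6) sp <- sp[1L]
  volume3d(vals, voxel_size_mm = sp,
           intensity_range = range(vals))
}

#' @param vol a [volume3d()] (or 3D array).
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume3d(vol)
  sp <- vol$voxel_size_mm
  if (length(sp) == 1L) sp <- rep(sp, 3L)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- sp
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}
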