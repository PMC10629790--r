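#' Volumetric image container
#'
#' Bundles a 3-D scalar lattice with the 4x4 affine that maps 0-based voxel
#' indices to world (mm) coordinates, plus a boolean analysis mask of the
#' same shape. All downstream operations read data only where the mask is
#' TRUE.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 numeric matrix, homogeneous voxel-index -> mm transform.
#'   Must be invertible.
#' @param mask logical array of the same shape as `data`; default all TRUE.
#' @return An object of class `volume_image` with elements `data`, `affine`,
#'   `mask`.
#' @export
volume_image <- function(data, affine = diag(4), mask = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("`affine` is not invertible")
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  if (!identical(dim(mask), dim(data)))
    stop("`mask` shape must equal `data` shape")
  structure(list(data = data, affine = affine, mask = array(as.logical(mask), dim(data))),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$mask), " in mask\n", sep = "")
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @param mask optional logical array to attach; default: finite, non-NA voxels.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path, "': ",
                                           conditionMessage(e)))
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  dat <- array(as.numeric(img), dim = dim(img)[1:3])
  if (abs(det(aff)) < .Machine$double.eps * 64)
    stop("non-invertible affine in '", path, "'")
  if (is.null(mask)) mask <- array(is.finite(dat), dim(dat))
  volume_image(dat, aff, mask)
}

#' Write a volume as NIfTI-1
#'
#' Round trips preserve the data to float32 precision and the affine exactly.
#'
#' @param img a [volume_image()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image"))
  nim <- RNifti::asNifti(img$data)
  nim <- RNifti::`sform<-`(nim, structure(img$affine, code = 2L))
  RNifti::writeNifti(nim, path, datatype = "double")
  invisible(path)
}

#' Map voxel indices to world coordinates
#'
#' @param img a [volume_image()].
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices
#'   (may be fractional).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(img, ijk) {
  ijk <- rbind_coords(ijk)
  h <- cbind(ijk, 1) %*% t(img$affine)
  h[, 1:3, drop = FALSE]
}

#' Map world coordinates to voxel indices
#'
#' @param img a [volume_image()].
#' @param xyz_mm n x 3 matrix (or length-3 vector) of world coordinates.
#' @return list with `continuous` (n x 3, 0-based fractional indices),
#'   `nearest` (n x 3 integer, round-half-to-even), and `inside_mask`
#'   (logical; FALSE when out of bounds or the mask is FALSE there).
#' @export
world_to_voxel <- function(img, xyz_mm) {
  xyz <- rbind_coords(xyz_mm)
  inv <- solve(img$affine)
  cont <- cbind(xyz, 1) %*% t(inv)
  cont <- cont[, 1:3, drop = FALSE]
  near <- round(cont)  # round-half-to-even; ties measure-zero in practice
  dims <- dim(img$data)
  inb <- near[, 1] >= 0 & near[, 1] < dims[1] &
         near[, 2] >= 0 & near[, 2] < dims[2] &
         near[, 3] >= 0 & near[, 3] < dims[3]
  inside <- logical(nrow(near))
  if (any(inb)) {
    idx <- near[inb, , drop = FALSE] + 1L
    inside[inb] <- img$mask[cbind(idx[, 1], idx[, 2], idx[, 3])]
  }
  list(continuous = cont, nearest = near, inside_mask = inside)
}

#' Look up voxel values at world coordinates (nearest voxel)
#'
#' @param img a [volume_image()].
#' @param xyz_mm n x 3 matrix of world coordinates.
#' @return list with `values` (NA where outside the mask) and `inside_mask`.
#' @export
sample_at <- function(img, xyz_mm) {
  w <- world_to_voxel(img, xyz_mm)
  vals <- rep(NA_real_, nrow(w$nearest))
  if (any(w$inside_mask)) {
    idx <- w$nearest[w$inside_mask, , drop = FALSE] + 1L
    vals[w$inside_mask] <- img$data[cbind(idx[, 1], idx[, 2], idx[, 3])]
  }
  list(values = vals, inside_mask = w$inside_mask)
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  if (!all(is.finite(x))) stop("coordinates must be finite")
  x
}

#' Read / write a coordinate table
#'
#' Tab-separated with at least columns `id`, `x_mm`, `y_mm`, `z_mm`; extra
#' columns carried through as attributes.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_coordinate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(tab[, c("x_mm", "y_mm", "z_mm")]))))
    stop("non-finite coordinates in ", path)
  tab
}

#' @rdname read_coordinate_table
#' @param tab data.frame with id and mm coordinate columns.
#' @export
write_coordinate_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
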