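#' Voxel grids and axial fields
#'
#' Volumes are plain 3D arrays plus a voxel-to-world affine (NIfTI
#' convention: 4 x 4 matrix mapping 0-based voxel indices to world mm).
#' An `axial_field` stores one optional unit axis per voxel together with a
#' validity mask.
#'
#' @name grids
NULL

#' Default affine for an isotropic-or-not grid centred at the origin of
#' voxel (0,0,0)
#' @param voxel_mm length-3 voxel size in mm.
#' @keywords internal
default_affine <- function(voxel_mm) {
  voxel_mm <- rep(voxel_mm, length.out = 3)
  a <- diag(c(voxel_mm, 1))
  a
}

#' Construct an axial field
#'
#' @param axes numeric array of dim `c(dim, 3)`: per-voxel axis components.
#' @param mask logical array of dim `dim`: TRUE where an axis is defined.
#' @param voxel_mm length-3 voxel size (mm).
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices).
#' @return object of class `axial_field`.
#' @export
axial_field <- function(axes, mask, voxel_mm,
                        affine = default_affine(voxel_mm)) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3, identical(dim(axes), c(dm, 3L)),
            is.logical(mask))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be invertible", call. = FALSE)
  }
  structure(list(axes = axes, mask = mask,
                 voxel_mm = rep(voxel_mm, length.out = 3),
                 affine = affine, dim = dm),
            class = "axial_field")
}

#' @export
print.axial_field <- function(x, ...) {
  cat("<axial_field> grid", paste(x$dim, collapse = " x "),
      "voxels,", paste(signif(x$voxel_mm, 3), collapse = " x "), "mm;",
      sum(x$mask), "valid voxels\n")
  invisible(x)
}

#' @export
dim.axial_field <- function(x) x$dim

#' Matrix of valid axes of an axial field
#'
#' @param field an `axial_field`.
#' @return n x 3 matrix, one row per valid voxel (array order).
#' @export
field_axes_matrix <- function(field) {
  idx <- which(field$mask)
  n <- prod(field$dim)
  cbind(field$axes[idx], field$axes[idx + n], field$axes[idx + 2L * n])
}

#' Build an axial field from a matrix of axes at given linear voxel indices
#' @keywords internal
field_from_matrix <- function(ax_mat, idx, dm, voxel_mm, affine) {
  axes <- array(NA_real_, c(dm, 3L))
  mask <- array(FALSE, dm)
  n <- prod(dm)
  mask[idx] <- TRUE
  axes[idx] <- ax_mat[, 1]
  axes[idx + n] <- ax_mat[, 2]
  axes[idx + 2L * n] <- ax_mat[, 3]
  axial_field(axes, mask, voxel_mm, affine)
}

#' World coordinates of voxel centers
#'
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param affine 4 x 4 voxel-to-world matrix over 0-based indices.
#' @return n x 3 matrix of world mm coordinates.
#' @keywords internal
voxel_to_world <- function(ijk, affine) {
  ijk0 <- cbind(ijk - 1, 1)
  xyz <- ijk0 %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Voxel indices (1-based, real-valued) of world coordinates
#' @keywords internal
world_to_voxel <- function(xyz, affine) {
  inv <- solve(affine)
  ijk0 <- cbind(xyz, 1) %*% t(inv)
  ijk0[, 1:3, drop = FALSE] + 1
}

#' Tidy an axial field into a tibble
#'
#' One row per valid voxel with voxel indices, world coordinates and axis
#' components (canonical sign).
#'
#' @param x an `axial_field`.
#' @param ... unused.
#' @return tibble with columns i, j, k, x, y, z, ax, ay, az.
#' @export
tidy.axial_field <- function(x, ...) {
  idx <- which(x$mask)
  ijk <- arrayInd(idx, x$dim)
  xyz <- voxel_to_world(ijk, x$affine)
  axm <- axis_canonical(field_axes_matrix(x))
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 ax = axm[, 1], ay = axm[, 2], az = axm[, 3])
}

#' Read / write an axial field as NIfTI
#'
#' The axis components are stored as a 4D volume (last dimension 3) and the
#' validity mask as a companion 3D volume; invalid voxels hold zeros.
#'
#' @param field an `axial_field`.
#' @param axes_path,mask_path file paths (`.nii` or `.nii.gz`).
#' @return `write_axial_field` returns the paths invisibly;
#'   `read_axial_field` returns an `axial_field`.
#' @export
write_axial_field <- function(field, axes_path, mask_path) {
  ax <- field$axes
  ax[is.na(ax)] <- 0
  img <- RNifti::asNifti(ax)
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, axes_path)
  msk <- RNifti::asNifti(array(as.numeric(field$mask), dim(field$mask)))
  msk <- RNifti::`sform<-`(msk, structure(field$affine, code = 2L))
  RNifti::writeNifti(msk, mask_path)
  invisible(c(axes_path, mask_path))
}

#' @rdname write_axial_field
#' @export
read_axial_field <- function(axes_path, mask_path) {
  img <- RNifti::readNifti(axes_path)
  msk <- RNifti::readNifti(mask_path)
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  axes <- array(as.numeric(img), dim(img))
  mask <- array(as.numeric(msk) > 0.5, dim(msk))
  axes_na <- axes
  for (c3 in 1:3) {
    comp <- axes_na[, , , c3]
    comp[!mask] <- NA_real_
    axes_na[, , , c3] <- comp
  }
  axial_field(axes_na, mask, voxel_mm, affine)
}

#' Read / write a scalar volume as NIfTI
#'
#' Thin wrappers keeping the voxel-to-world affine attached.
#' @param vol 3D array with optional `affine` attribute.
#' @param path file path.
#' @export
write_volume <- function(vol, path, affine = attr(vol, "affine"),
                         voxel_mm = attr(vol, "voxel_mm")) {
  if (is.null(affine)) affine <- default_affine(voxel_mm %||% 1)
  img <- RNifti::asNifti(unclass(vol))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim(img))
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  attr(vol, "affine") <- aff
  attr(vol, "voxel_mm") <- sqrt(colSums(aff[1:3, 1:3]^2))
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
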