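#' Volume grid: a 3D/4D array with a voxel-to-world affine
#'
#' The spatial substrate shared by masks, diffusion signal and tensor maps.
#' Voxel indices are 0-based; the voxel centre of index `(i, j, k)` sits at
#' `affine %*% c(i, j, k, 1)` in world (RAS) millimetres, with world `x > 0`
#' on the right.
#'
#' @param data numeric or logical array with 3 or 4 dimensions. For 4D data
#'   the first three dimensions are spatial.
#' @param affine invertible 4x4 matrix mapping homogeneous 0-based voxel
#'   indices to world mm.
#' @return An object of class `volume_grid` with elements `data`, `affine`.
#' @export
volume_grid <- function(data, affine) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array", call. = FALSE)
  affine <- validate_affine(affine)
  structure(list(data = data, affine = affine), class = "volume_grid")
}

validate_affine <- function(affine) {
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < 1e-12)
    stop("affine is not invertible", call. = FALSE)
  if (any(voxel_size_affine(affine) <= 0))
    stop("voxel size derived from affine must be strictly positive", call. = FALSE)
  storage.mode(affine) <- "double"
  affine
}

voxel_size_affine <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @rdname volume_grid
#' @param grid a `volume_grid`
#' @export
voxel_size <- function(grid) voxel_size_affine(grid$affine)

#' @rdname volume_grid
#' @export
grid_shape <- function(grid) dim(grid$data)[1:3]

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_grid> ", paste(d, collapse = " x "),
      " | voxel size ", paste(signif(voxel_size(x), 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

## internal: apply a 4x4 affine to an n x 3 matrix of points
apply_affine <- function(affine, pts) {
  pts <- as_points(pts)
  out <- pts %*% t(affine[1:3, 1:3])
  sweep(out, 2, affine[1:3, 4], `+`)
}

as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("points must be n x 3", call. = FALSE)
  x
}

#' Voxel/world coordinate transforms
#'
#' `voxel_to_world()` maps 0-based voxel indices to world mm through the
#' grid's affine; `world_to_voxel()` inverts it, rounding to the nearest
#' lattice index by default.
#'
#' @param grid a [volume_grid()]
#' @param ijk integer voxel indices (vector of 3 or n x 3 matrix, 0-based)
#' @param xyz world coordinates in mm (vector of 3 or n x 3 matrix)
#' @param round round to the nearest integer index (default `TRUE`); with
#'   `FALSE` the continuous index-space coordinate is returned.
#' @return n x 3 matrix of coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- as_points(ijk)
  shp <- grid_shape(grid)
  if (any(ijk < -0.5) || any(sweep(ijk, 2, shp - 0.5, `>=`)))
    stop("voxel index out of bounds for grid of shape ",
         paste(shp, collapse = "x"), call. = FALSE)
  apply_affine(grid$affine, ijk)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz, round = TRUE) {
  ijk <- apply_affine(solve(grid$affine), as_points(xyz))
  if (round) round(ijk) else ijk
}

in_bounds <- function(grid, ijk) {
  shp <- grid_shape(grid)
  ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
    ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
    ijk[, 3] >= 0 & ijk[, 3] < shp[3]
}

#' Binary region-of-interest mask
#'
#' A `volume_grid` carrying logical data plus a label and hemisphere tag.
#' For left/right masks the hemisphere must be consistent with the sign of
#' the world-x centre of gravity (RAS: x > 0 is right); `"auto"` derives it.
#'
#' @param data logical 3D array (or coercible)
#' @param affine 4x4 voxel-to-world matrix
#' @param name label string
#' @param hemisphere one of `"left"`, `"right"`, `"midline"`, `"auto"`
#' @param allow_empty permit a mask with no TRUE voxel
#' @return An object of class `binary_mask` (also a `volume_grid`).
#' @export
binary_mask <- function(data, affine, name = "roi",
                        hemisphere = c("auto", "left", "right", "midline"),
                        allow_empty = FALSE) {
  hemisphere <- match.arg(hemisphere)
  storage.mode(data) <- "logical"
  g <- volume_grid(data, affine)
  n_true <- sum(g$data)
  if (n_true == 0 && !allow_empty)
    stop("mask '", name, "' has no TRUE voxel (use allow_empty = TRUE)", call. = FALSE)
  cog_x <- if (n_true > 0) mean(mask_centres(g)[, 1]) else NA_real_
  if (hemisphere == "auto") {
    half_vox <- voxel_size_affine(g$affine)[1] / 2
    hemisphere <- if (is.na(cog_x) || abs(cog_x) < half_vox) "midline"
      else if (cog_x < 0) "left" else "right"
  } else if (hemisphere %in% c("left", "right") && n_true > 0) {
    ok <- (hemisphere == "left" && cog_x < 0) || (hemisphere == "right" && cog_x > 0)
    if (!ok) stop("hemisphere '", hemisphere, "' inconsistent with mask centre of gravity (x = ",
                  signif(cog_x, 4), " mm)", call. = FALSE)
  }
  g$name <- name
  g$hemisphere <- hemisphere
  class(g) <- c("binary_mask", class(g))
  g
}

#' @rdname binary_mask
#' @param mask a `binary_mask` (or logical `volume_grid`)
#' @return `mask_centres()`: n x 3 matrix of world coordinates of TRUE voxels.
#' @export
mask_centres <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), ncol = 3))
  apply_affine(mask$affine, idx - 1)  # 1-based array index -> 0-based voxel
}

#' Read/write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving the voxel-to-world affine exactly
#' through a round trip (stored in the sform).
#'
#' @param path file path (`.nii` or `.nii.gz`)
#' @param grid a [volume_grid()] or [binary_mask()]
#' @return `read_volume()` returns a `volume_grid`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  arr <- array(as.numeric(img), dim = dim(img))
  volume_grid(arr, validate_affine(aff))
}

#' @rdname read_volume
#' @export
write_volume <- function(grid, path) {
  dat <- grid$data
  if (is.logical(dat)) {
    dat <- dat * 1L
    storage.mode(dat) <- "integer"
  }
  img <- RNifti::asNifti(dat, pixdim = voxel_size(grid))
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
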