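#' Multi-fiber orientation fields
#'
#' Per voxel, up to two fiber populations, each described by a unit mean
#' direction, a volume fraction in `[0, 1]` and an angular concentration
#' `kappa`. `kappa` parameterises a Watson-like axial dispersion: sampled
#' directions are the mean direction plus isotropic Gaussian noise of
#' standard deviation `1/sqrt(2*kappa)`, renormalised. `kappa = Inf` (and,
#' as a convenience for orientation formats that carry no dispersion,
#' `kappa = 0`) means no dispersion is modelled. Fractions per voxel must
#' sum to at most 1; a zero fraction marks an absent population.
#'
#' @param dir1,dir2 4D arrays `nx x ny x nz x 3` of mean directions
#'   (unit-norm wherever the matching fraction is positive).
#' @param f1,f2 3D arrays of volume fractions.
#' @param kappa1,kappa2 3D arrays (or scalars, recycled) of concentrations.
#' @param affine An [affine_transform()].
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(dir1, f1, dir2 = NULL, f2 = NULL,
                              kappa1 = Inf, kappa2 = Inf, affine) {
  dm <- dim(f1)
  stopifnot(length(dm) == 3L, identical(dim(dir1), c(dm, 3L)))
  if (is.null(dir2)) dir2 <- array(0, c(dm, 3L))
  if (is.null(f2)) f2 <- array(0, dm)
  stopifnot(identical(dim(dir2), c(dm, 3L)), identical(dim(f2), dm))
  if (length(kappa1) == 1L) kappa1 <- array(kappa1, dm)
  if (length(kappa2) == 1L) kappa2 <- array(kappa2, dm)
  if (any(f1 < 0) || any(f2 < 0) || any(f1 + f2 > 1 + 1e-9)) {
    stop("volume fractions must be nonnegative and sum to <= 1 per voxel",
      call. = FALSE
    )
  }
  check_unit <- function(d, f) {
    nrm2 <- d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2
    bad <- f > 0 & abs(nrm2 - 1) > 1e-6
    if (any(bad)) {
      stop("directions must be unit-norm where the fraction is positive",
        call. = FALSE
      )
    }
  }
  check_unit(dir1, f1)
  check_unit(dir2, f2)
  structure(
    list(
      dim = dm, dir1 = dir1, f1 = f1, dir2 = dir2, f2 = f2,
      kappa1 = kappa1, kappa2 = kappa2, affine = affine
    ),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  nfib <- sum(x$f1 > 0) + sum(x$f2 > 0)
  cat(
    "<orientation_field> ", paste(x$dim, collapse = " x "),
    " voxels, ", sum(x$f1 > 0), " single-population voxels, ",
    sum(x$f2 > 0), " crossing voxels (", nfib, " populations)\n",
    sep = ""
  )
  invisible(x)
}

# Flattened view used by the tracking engine: directions as nvox x 3
# matrices, fractions and kappas as vectors over the linear voxel index.
flatten_field <- function(field) {
  nvox <- prod(field$dim)
  list(
    dim = field$dim,
    D1 = matrix(field$dir1, nvox, 3L),
    D2 = matrix(field$dir2, nvox, 3L),
    f1 = as.vector(field$f1),
    f2 = as.vector(field$f2),
    k1 = as.vector(field$kappa1),
    k2 = as.vector(field$kappa2)
  )
}

#' Read and write orientation fields as 4D NIfTI
#'
#' The field is serialised as a 4D volume with ten 3D components: for each
#' of the two populations, three direction components, the volume fraction
#' and the concentration `kappa` (with `Inf` stored as `-1`).
#'
#' @param field An [orientation_field()].
#' @param path NIfTI file path.
#' @export
write_orientation_field <- function(field, path) {
  dm <- field$dim
  arr <- array(0, c(dm, 10L))
  arr[, , , 1:3] <- field$dir1
  arr[, , , 4] <- field$f1
  arr[, , , 5] <- ifelse(is.finite(field$kappa1), field$kappa1, -1)
  arr[, , , 6:8] <- field$dir2
  arr[, , , 9] <- field$f2
  arr[, , , 10] <- ifelse(is.finite(field$kappa2), field$kappa2, -1)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(unclass(field$affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(field)
}

#' @rdname write_orientation_field
#' @export
read_orientation_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  stopifnot(length(dim(arr)) == 4L, dim(arr)[4] == 10L)
  unfix <- function(k) ifelse(k < 0, Inf, k)
  orientation_field(
    dir1 = arr[, , , 1:3, drop = FALSE],
    f1 = arr[, , , 4],
    dir2 = arr[, , , 6:8, drop = FALSE],
    f2 = arr[, , , 9],
    kappa1 = unfix(arr[, , , 5]),
    kappa2 = unfix(arr[, , , 10]),
    affine = affine_transform(RNifti::xform(img))
  )
}
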