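#' Voxel-to-world affine transforms
#'
#' An `affine_transform` is a 4x4 matrix mapping *continuous* 0-based voxel
#' coordinates to world millimetre coordinates. Voxel `(i, j, k)` occupies
#' the half-open box `[i, i+1) x [j, j+1) x [k, k+1)` in continuous voxel
#' space, so its centre sits at `(i, j, k) + 0.5`. World-to-voxel mapping
#' applies the inverse affine and then *floors* each coordinate; this floor
#' (not round) convention is used everywhere in the package.
#'
#' @param mat A 4x4 numeric matrix; must be invertible.
#' @return An object of class `affine_transform` (a 4x4 matrix).
#' @export
#' @examples
#' aff <- affine_transform(diag(4))
#' world_to_voxel(aff, c(2.2, 3.7, 0))
affine_transform <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(is.numeric(mat), all(dim(mat) == c(4L, 4L)))
  d <- det(mat)
  if (!is.finite(d) || abs(d) < 1e-12) {
    stop("affine matrix is singular", call. = FALSE)
  }
  structure(mat, class = c("affine_transform", "matrix"))
}

#' @rdname affine_transform
#' @param spacing Voxel edge lengths in mm (length 3).
#' @param origin World coordinate of continuous voxel coordinate (0,0,0).
#' @export
affine_from_spacing <- function(spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  m <- diag(4)
  diag(m)[1:3] <- spacing
  m[1:3, 4] <- origin
  affine_transform(m)
}

apply_affine <- function(mat, pts) {
  pts <- rbind(t(pts), 1)
  out <- mat %*% pts
  t(out[1:3, , drop = FALSE])
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    points <- matrix(points, nrow = 1L)
  }
  stopifnot(ncol(points) == 3L)
  points
}

#' Map world coordinates to voxel indices
#'
#' Applies the inverse affine and floors each continuous coordinate to a
#' 0-based voxel index. When `dim` is supplied, points falling outside the
#' grid are flagged out-of-bounds and their indices set to `NA`.
#'
#' @param affine An [affine_transform()].
#' @param points World coordinates: a length-3 vector or an n x 3 matrix.
#' @param dim Optional grid shape (3 integers) for the bounds check.
#' @return An n x 3 integer matrix of 0-based voxel indices; rows of `NA`
#'   signal out-of-bounds points (only when `dim` is given).
#' @export
world_to_voxel <- function(affine, points, dim = NULL) {
  points <- as_points(points)
  cont <- apply_affine(solve(unclass(affine)), points)
  vox <- floor(cont)
  storage.mode(vox) <- "integer"
  if (!is.null(dim)) {
    ok <- in_grid(vox, dim)
    vox[!ok, ] <- NA_integer_
  }
  vox
}

#' @rdname world_to_voxel
#' @param voxels 0-based voxel index triples (vector or n x 3 matrix).
#' @return For `voxel_center_world()`: the world coordinates of the voxel
#'   centres (indices + 0.5 pushed through the affine).
#' @export
voxel_center_world <- function(affine, voxels) {
  voxels <- as_points(voxels)
  apply_affine(unclass(affine), voxels + 0.5)
}

#' ROI registries
#'
#' A registry is an ordered tibble with columns `label` (positive integer),
#' `name` (structure name) and `hemisphere` (`"left"`, `"right"` or
#' `"midline"`). The (name, hemisphere) pair must be unique and a bilateral
#' structure appears exactly twice, once per hemisphere. Hemisphere is an
#' explicit attribute of each ROI rather than a midline coordinate test, so
#' the hemisphere-matched task enumeration is robust to asymmetric phantoms.
#'
#' @param label Integer labels (distinct, positive).
#' @param name Structure names.
#' @param hemisphere One of `"left"`, `"right"`, `"midline"` per row.
#' @return A tibble of class `roi_registry`.
#' @export
#' @examples
#' default_roi_registry()
roi_registry <- function(label, name, hemisphere) {
  reg <- tibble::tibble(
    label = as.integer(label),
    name = as.character(name),
    hemisphere = as.character(hemisphere)
  )
  stopifnot(
    all(reg$label > 0L), !anyDuplicated(reg$label),
    all(reg$hemisphere %in% c("left", "right", "midline"))
  )
  if (anyDuplicated(reg[, c("name", "hemisphere")])) {
    stop("duplicate (name, hemisphere) pair in ROI registry", call. = FALSE)
  }
  for (nm in unique(reg$name)) {
    hemis <- sort(reg$hemisphere[reg$name == nm])
    ok <- identical(hemis, "midline") || identical(hemis, "left") ||
      identical(hemis, "right") || identical(hemis, c("left", "right"))
    if (!ok) {
      stop(sprintf(
        "structure '%s': hemisphere tags must be midline, one side, or left+right",
        nm
      ), call. = FALSE)
    }
  }
  class(reg) <- c("roi_registry", class(reg))
  reg
}

#' @rdname roi_registry
#' @details `default_roi_registry()` returns the 15-region roster used by
#'   the default phantom: seven bilateral structures (hippocampus,
#'   nucleus accumbens, amygdala, caudate nucleus, globus pallidus,
#'   putamen, thalamus) plus a midline brainstem.
#' @export
default_roi_registry <- function() {
  bilat <- c(
    "hippocampus", "nucleus_accumbens", "amygdala", "caudate_nucleus",
    "globus_pallidus", "putamen", "thalamus"
  )
  roi_registry(
    label = seq_len(15L),
    name = c(rep(bilat, each = 2L), "brainstem"),
    hemisphere = c(rep(c("left", "right"), times = 7L), "midline")
  )
}

#' Label volumes
#'
#' A label volume couples a 3D integer lattice (0 = background) with an
#' affine and an ROI registry describing each nonzero label.
#'
#' @param lattice 3D integer array of labels (0 background).
#' @param affine An [affine_transform()].
#' @param registry An [roi_registry()] covering every nonzero label present.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(lattice, affine, registry) {
  stopifnot(length(dim(lattice)) == 3L, inherits(affine, "affine_transform"))
  storage.mode(lattice) <- "integer"
  if (any(lattice < 0L)) stop("labels must be nonnegative", call. = FALSE)
  present <- setdiff(sort(unique(as.vector(lattice))), 0L)
  missing <- setdiff(present, registry$label)
  if (length(missing)) {
    stop(
      "labels present in lattice but absent from registry: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(lattice = lattice, affine = affine, registry = registry),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat(
    "<label_volume> ", paste(dim(x$lattice), collapse = " x "),
    " voxels, ", nrow(x$registry), " registered ROIs\n",
    sep = ""
  )
  invisible(x)
}

#' Voxels carrying one ROI label
#'
#' @param volume A [label_volume()].
#' @param label A registered label.
#' @return An n x 3 integer matrix of 0-based voxel indices (possibly 0 rows).
#' @export
roi_voxels <- function(volume, label) {
  stopifnot(inherits(volume, "label_volume"))
  if (!label %in% volume$registry$label) {
    stop(sprintf("label %s is not in the ROI registry", label), call. = FALSE)
  }
  idx <- which(volume$lattice == label, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  idx - 1L
}

# label lookup by (name, hemisphere)
roi_label <- function(registry, name, hemisphere) {
  hit <- registry$label[registry$name == name & registry$hemisphere == hemisphere]
  if (length(hit) != 1L) {
    stop(sprintf("no unique ROI '%s' (%s) in registry", name, hemisphere),
      call. = FALSE
    )
  }
  hit
}

#' Read and write label volumes and registries
#'
#' Label volumes are stored as NIfTI with the affine in the sform; the
#' registry travels as a sidecar TSV with columns label, name, hemisphere.
#'
#' @param volume A [label_volume()].
#' @param nifti_path,registry_path Output/input file paths.
#' @export
write_label_volume <- function(volume, nifti_path, registry_path) {
  img <- RNifti::asNifti(volume$lattice)
  img <- RNifti::`sform<-`(img, structure(unclass(volume$affine), code = 2L))
  RNifti::writeNifti(img, nifti_path)
  readr::write_tsv(tibble::as_tibble(volume$registry), registry_path)
  invisible(volume)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(nifti_path, registry_path) {
  img <- RNifti::readNifti(nifti_path)
  reg <- readr::read_tsv(registry_path, show_col_types = FALSE)
  lattice <- array(as.integer(round(img)), dim = dim(img))
  label_volume(
    lattice,
    affine_transform(RNifti::xform(img)),
    roi_registry(reg$label, reg$name, reg$hemisphere)
  )
}
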