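#' Phantom configuration
#'
#' Describes a synthetic brain phantom: a voxel grid, a roster of spherical
#' ROIs (each tagged left/right/midline), curved fiber tracts as tubes
#' around spline centerlines, and optional crossing boxes in which two
#' fiber populations coexist. All geometry is expressed in continuous
#' 0-based voxel coordinates; the affine places the grid in world mm space.
#'
#' @param grid_shape Grid dimensions in voxels (3 positive integers).
#' @param spacing Voxel spacing in mm (length 3).
#' @param origin World coordinate of continuous voxel coordinate (0,0,0).
#' @param rois Tibble with columns `name`, `hemisphere`, `cx`, `cy`, `cz`
#'   (sphere centre, continuous voxel coords) and `radius` (voxels).
#' @param tracts Tibble with columns `tract_id`, `seed`, `target`,
#'   `hemisphere`, `ctrl` (list column of m x 3 control-point matrices),
#'   `radius` (tube radius, voxels) and `fraction` (fiber volume fraction).
#' @param crossings Tibble with columns `tract_a`, `tract_b`, box bounds
#'   `xmin`..`zmax` (continuous voxel coords) and fractions `f_a`, `f_b`.
#'   Inside a crossing box every voxel carries two populations whose
#'   directions follow the local tangents of the two named tracts.
#' @param kappa Angular concentration given to every fiber population.
#' @param seed RNG seed recorded with the phantom.
#' @return An object of class `phantom_config`.
#' @seealso [default_phantom_config()], [make_phantom()]
#' @export
phantom_config <- function(grid_shape = c(48L, 56L, 48L),
                           spacing = c(1, 1, 1),
                           origin = c(-24, -28, -24),
                           rois,
                           tracts = NULL,
                           crossings = NULL,
                           kappa = 40,
                           seed = 0L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  grid_shape <- as.integer(grid_shape)
  if (is.null(tracts)) {
    tracts <- tibble::tibble(
      tract_id = character(), seed = character(), target = character(),
      hemisphere = character(), ctrl = list(),
      radius = numeric(), fraction = numeric()
    )
  }
  if (is.null(crossings)) {
    crossings <- tibble::tibble(
      tract_a = character(), tract_b = character(),
      xmin = numeric(), xmax = numeric(), ymin = numeric(), ymax = numeric(),
      zmin = numeric(), zmax = numeric(), f_a = numeric(), f_b = numeric()
    )
  }
  cfg <- structure(
    list(
      grid_shape = grid_shape, spacing = spacing, origin = origin,
      rois = rois, tracts = tracts, crossings = crossings,
      kappa = kappa, seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  rois <- cfg$rois
  stopifnot(all(c("name", "hemisphere", "cx", "cy", "cz", "radius") %in% names(rois)))
  ctr <- as.matrix(rois[, c("cx", "cy", "cz")])
  lo <- ctr - rois$radius
  hi <- ctr + rois$radius
  if (any(lo < 0) || any(t(t(hi) > cfg$grid_shape))) {
    stop("ROI sphere extends outside the grid", call. = FALSE)
  }
  for (t in seq_len(nrow(cfg$tracts))) {
    tr <- cfg$tracts[t, ]
    ctrlm <- tr$ctrl[[1]]
    for (end in c("seed", "target")) {
      nm <- tr[[end]]
      row <- rois[rois$name == nm & rois$hemisphere == tr$hemisphere, ]
      if (nrow(row) != 1L) {
        stop(sprintf(
          "tract '%s': %s ROI '%s' (%s) not found",
          tr$tract_id, end, nm, tr$hemisphere
        ), call. = FALSE)
      }
      pt <- ctrlm[if (end == "seed") 1L else nrow(ctrlm), ]
      d <- sqrt(sum((pt - c(row$cx, row$cy, row$cz))^2))
      if (d > row$radius) {
        stop(sprintf(
          "tract '%s': %s endpoint lies outside ROI '%s'",
          tr$tract_id, end, nm
        ), call. = FALSE)
      }
    }
  }
  for (x in seq_len(nrow(cfg$crossings))) {
    cr <- cfg$crossings[x, ]
    for (tid in c(cr$tract_a, cr$tract_b)) {
      if (!tid %in% cfg$tracts$tract_id) {
        stop(sprintf("crossing references unknown tract '%s'", tid),
          call. = FALSE
        )
      }
    }
  }
  invisible(cfg)
}

#' @rdname phantom_config
#' @details `default_phantom_config()` builds the study-layout phantom:
#'   a 48 x 56 x 48 grid at 1 mm spacing with a bilateral
#'   hippocampus-analog seed, six bilateral targets (nucleus accumbens,
#'   amygdala, caudate nucleus, globus pallidus, putamen, thalamus
#'   analogs) and a midline brainstem-analog (15 ROIs in total). Tracts
#'   run from the seed to five of the six targets per hemisphere; the
#'   accumbens-analog is deliberately unconnected in both hemispheres, so
#'   10 of the 12 enumerated seed-target tasks carry fibers. One crossing
#'   box sits where the left caudate- and putamen-bound tracts intersect.
#' @export
default_phantom_config <- function(seed = 0L) {
  mirror <- function(p) c(47 - p[1], p[2], p[3])
  left <- list(
    hippocampus = c(14, 20, 20), nucleus_accumbens = c(10, 40, 18),
    amygdala = c(14, 30, 16), caudate_nucleus = c(9, 36, 26),
    globus_pallidus = c(14, 40, 24), putamen = c(19, 36, 24),
    thalamus = c(14, 24, 32)
  )
  radii <- c(
    hippocampus = 2.5, nucleus_accumbens = 2, amygdala = 2,
    caudate_nucleus = 2, globus_pallidus = 2, putamen = 2, thalamus = 2.5
  )
  roi_rows <- list()
  for (nm in names(left)) {
    roi_rows[[length(roi_rows) + 1L]] <- tibble::tibble(
      name = nm, hemisphere = c("left", "right"),
      cx = c(left[[nm]][1], mirror(left[[nm]])[1]),
      cy = left[[nm]][2], cz = left[[nm]][3], radius = radii[[nm]]
    )
  }
  roi_rows[[length(roi_rows) + 1L]] <- tibble::tibble(
    name = "brainstem", hemisphere = "midline",
    cx = 23.5, cy = 16, cz = 8, radius = 3
  )
  rois <- dplyr::bind_rows(roi_rows)

  mids <- list(
    amygdala = c(14, 25, 17), caudate_nucleus = c(18, 28, 24),
    globus_pallidus = c(8, 30, 19), putamen = c(10, 28, 22),
    thalamus = c(14, 21, 26)
  )
  tract_rows <- list()
  for (hemi in c("left", "right")) {
    s <- left$hippocampus
    if (hemi == "right") s <- mirror(s)
    for (tg in names(mids)) {
      a <- left[[tg]]
      m <- mids[[tg]]
      if (hemi == "right") {
        a <- mirror(a)
        m <- mirror(m)
      }
      tract_rows[[length(tract_rows) + 1L]] <- tibble::tibble(
        tract_id = paste(hemi, "hippocampus", tg, sep = "_"),
        seed = "hippocampus", target = tg, hemisphere = hemi,
        ctrl = list(rbind(s, m, a)), radius = 1.5, fraction = 0.6
      )
    }
  }
  tracts <- dplyr::bind_rows(tract_rows)

  crossings <- tibble::tibble(
    tract_a = "left_hippocampus_caudate_nucleus",
    tract_b = "left_hippocampus_putamen",
    xmin = 11, xmax = 17, ymin = 29, ymax = 33, zmin = 20, zmax = 27,
    f_a = 0.4, f_b = 0.4
  )

  phantom_config(
    rois = rois, tracts = tracts, crossings = crossings, seed = seed
  )
}

# Densely resample a control polygon with natural cubic splines over the
# cumulative chord-length parameter; returns points and unit tangents.
dense_centerline <- function(ctrl, step = 0.25) {
  ctrl <- as.matrix(ctrl)
  if (nrow(ctrl) < 2L) stop("centerline needs >= 2 control points", call. = FALSE)
  s <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  n <- max(2L, ceiling(s[length(s)] / step) + 1L)
  u <- seq(0, s[length(s)], length.out = n)
  pts <- sapply(1:3, function(a) {
    if (nrow(ctrl) == 2L) {
      approx(s, ctrl[, a], xout = u)$y
    } else {
      spline(s, ctrl[, a], xout = u, method = "natural")$y
    }
  })
  tang <- rbind(pts[2, ] - pts[1, ], (pts[-(1:2), , drop = FALSE] -
    pts[seq_len(n - 2L), , drop = FALSE]) / 2, pts[n, ] - pts[n - 1L, ])
  list(points = pts, tangents = unit_rows(tang))
}

# Mark, for one tract, the voxels whose centres lie within `radius` of the
# centerline; returns linear indices, the min distance and the tangent at
# the closest centerline point.
tube_voxels <- function(center, dim, radius) {
  pts <- center$points
  tang <- center$tangents
  if (any(pts - radius < 0) || any(t(t(pts) + radius > dim))) {
    stop("tract tube exits the grid", call. = FALSE)
  }
  r_int <- ceiling(radius + 0.5)
  off <- as.matrix(expand.grid(
    i = -r_int:r_int, j = -r_int:r_int, k = -r_int:r_int
  ))
  off <- off[rowSums(off^2) <= (radius + 1)^2, , drop = FALSE]
  nvox <- prod(dim)
  best <- rep(Inf, nvox)
  best_t <- matrix(0, nvox, 3L)
  for (p in seq_len(nrow(pts))) {
    base <- floor(pts[p, ] - 0.5)
    vox <- sweep(off, 2L, base, "+")
    keep <- in_grid(vox, dim)
    vox <- vox[keep, , drop = FALSE]
    if (!nrow(vox)) next
    d <- sqrt(rowSums((sweep(vox + 0.5, 2L, pts[p, ], "-"))^2))
    sel <- d <= radius
    if (!any(sel)) next
    lin <- voxel_linear(vox[sel, , drop = FALSE], dim)
    d <- d[sel]
    better <- d < best[lin]
    lin <- lin[better]
    if (!length(lin)) next
    best[lin] <- d[better]
    best_t[lin, ] <- matrix(tang[p, ], length(lin), 3L, byrow = TRUE)
  }
  lin <- which(is.finite(best))
  list(lin = lin, dist = best[lin], tangent = best_t[lin, , drop = FALSE])
}

#' Build a phantom: label volume plus multi-fiber orientation field
#'
#' Paints each ROI sphere with a distinct positive label (overlapping
#' spheres are a hard error), fills each tract tube with one fiber
#' population tangent to its centerline, gives voxels shared by two tubes
#' both populations (fractions rescaled to sum to 0.9 when they would
#' exceed 1), applies crossing boxes as two-population regions following
#' the two named tracts' local tangents, and leaves all remaining voxels
#' with zero fiber fraction.
#'
#' @param config A [phantom_config()].
#' @return An object of class `fiberlink_phantom`: a list with elements
#'   `labels` ([label_volume()]), `field` ([orientation_field()]),
#'   `affine`, `config` and `centerlines` (dense per-tract centerlines
#'   kept for geometric ground-truth checks).
#' @export
#' @examples
#' ph <- make_phantom(default_phantom_config())
#' ph$labels
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dim3 <- config$grid_shape
  nvox <- prod(dim3)
  affine <- affine_from_spacing(config$spacing, config$origin)

  lattice <- array(0L, dim3)
  rois <- config$rois
  registry <- roi_registry(
    label = seq_len(nrow(rois)), name = rois$name, hemisphere = rois$hemisphere
  )
  idx_grid <- as.matrix(expand.grid(
    i = 0:(dim3[1] - 1L), j = 0:(dim3[2] - 1L), k = 0:(dim3[3] - 1L)
  ))
  for (r in seq_len(nrow(rois))) {
    ctr <- c(rois$cx[r], rois$cy[r], rois$cz[r])
    d2 <- (idx_grid[, 1] + 0.5 - ctr[1])^2 + (idx_grid[, 2] + 0.5 - ctr[2])^2 +
      (idx_grid[, 3] + 0.5 - ctr[3])^2
    inside <- which(d2 <= rois$radius[r]^2)
    if (any(lattice[inside] != 0L)) {
      stop(sprintf(
        "ROI '%s' (%s) overlaps an already painted ROI",
        rois$name[r], rois$hemisphere[r]
      ), call. = FALSE)
    }
    lattice[inside] <- r
  }

  f1 <- numeric(nvox)
  f2 <- numeric(nvox)
  D1 <- matrix(0, nvox, 3L)
  D2 <- matrix(0, nvox, 3L)
  centerlines <- list()
  tubes <- list()
  for (t in seq_len(nrow(config$tracts))) {
    tr <- config$tracts[t, ]
    cl <- dense_centerline(tr$ctrl[[1]])
    centerlines[[tr$tract_id]] <- cl
    tubes[[tr$tract_id]] <- tube_voxels(cl, dim3, tr$radius)
    tb <- tubes[[tr$tract_id]]
    for (n in seq_along(tb$lin)) {
      v <- tb$lin[n]
      if (f1[v] == 0) {
        f1[v] <- tr$fraction
        D1[v, ] <- tb$tangent[n, ]
      } else if (f2[v] == 0) {
        f2[v] <- tr$fraction
        D2[v, ] <- tb$tangent[n, ]
      } # a third tube in one voxel is dropped: at most two populations
    }
  }
  over <- f1 + f2 > 1
  if (any(over)) {
    scale <- 0.9 / (f1[over] + f2[over])
    f1[over] <- f1[over] * scale
    f2[over] <- f2[over] * scale
  }

  for (x in seq_len(nrow(config$crossings))) {
    cr <- config$crossings[x, ]
    inside <- which(
      idx_grid[, 1] + 0.5 >= cr$xmin & idx_grid[, 1] + 0.5 <= cr$xmax &
        idx_grid[, 2] + 0.5 >= cr$ymin & idx_grid[, 2] + 0.5 <= cr$ymax &
        idx_grid[, 3] + 0.5 >= cr$zmin & idx_grid[, 3] + 0.5 <= cr$zmax
    )
    if (!length(inside)) next
    ctrs <- idx_grid[inside, , drop = FALSE] + 0.5
    tangent_at <- function(tid) {
      cl <- centerlines[[tid]]
      nn <- apply(ctrs, 1L, function(p) {
        which.min(colSums((t(cl$points) - p)^2))
      })
      cl$tangents[nn, , drop = FALSE]
    }
    f1[inside] <- cr$f_a
    f2[inside] <- cr$f_b
    D1[inside, ] <- tangent_at(cr$tract_a)
    D2[inside, ] <- tangent_at(cr$tract_b)
  }

  kap1 <- ifelse(f1 > 0, config$kappa, Inf)
  kap2 <- ifelse(f2 > 0, config$kappa, Inf)
  field <- orientation_field(
    dir1 = array(D1, c(dim3, 3L)), f1 = array(f1, dim3),
    dir2 = array(D2, c(dim3, 3L)), f2 = array(f2, dim3),
    kappa1 = array(kap1, dim3), kappa2 = array(kap2, dim3),
    affine = affine
  )
  structure(
    list(
      labels = label_volume(lattice, affine, registry),
      field = field, affine = affine,
      config = config, centerlines = centerlines
    ),
    class = "fiberlink_phantom"
  )
}

#' @export
print.fiberlink_phantom <- function(x, ...) {
  cat(
    "<fiberlink_phantom> ", paste(x$config$grid_shape, collapse = " x "),
    " grid, ", nrow(x$config$rois), " ROIs, ",
    nrow(x$config$tracts), " tracts, ",
    nrow(x$config$crossings), " crossing box(es)\n",
    sep = ""
  )
  invisible(x)
}

# Distance from world/voxel points to a tract centerline; used for
# ground-truth in-tube flags and for geometric test oracles.
distance_to_tract <- function(phantom, points_vox, tract_id) {
  cl <- phantom$centerlines[[tract_id]]
  if (is.null(cl)) stop(sprintf("unknown tract '%s'", tract_id), call. = FALSE)
  apply(as_points(points_vox), 1L, function(p) {
    sqrt(min(colSums((t(cl$points) - p)^2)))
  })
}
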