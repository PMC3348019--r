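#' Tracking parameters
#'
#' @param step_size Euler step length in voxel units.
#' @param curvature_thresh Maximum turning angle per step, degrees
#'   (< 90 recommended, <= 180 required).
#' @param n_per_seed Streamline samples launched per seed voxel.
#' @param max_steps Maximum steps per propagation direction.
#' @param min_fraction Minimum volume fraction for a population to be
#'   eligible for sampling.
#' @param mask_threshold Minimum visitation count for a voxel to enter the
#'   binary pathway mask.
#' @param seed Master RNG seed for the tracking stage.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step_size = 0.5, curvature_thresh = 80,
                            n_per_seed = 100L, max_steps = 2000L,
                            min_fraction = 0.05, mask_threshold = 1L,
                            seed = 0L) {
  p <- structure(
    list(
      step_size = step_size, curvature_thresh = curvature_thresh,
      n_per_seed = as.integer(n_per_seed), max_steps = as.integer(max_steps),
      min_fraction = min_fraction, mask_threshold = as.integer(mask_threshold),
      seed = as.integer(seed)
    ),
    class = "tracking_params"
  )
  stopifnot(
    p$step_size > 0, p$curvature_thresh > 0, p$curvature_thresh <= 180,
    p$n_per_seed > 0, p$max_steps > 0, p$min_fraction > 0,
    p$mask_threshold > 0
  )
  p
}

# kappa -> sd of the isotropic Gaussian perturbation; Inf and 0 both mean
# "no dispersion modelled" (many orientation formats omit dispersion).
kappa_sd <- function(kappa) {
  out <- numeric(length(kappa))
  pos <- is.finite(kappa) & kappa > 0
  out[pos] <- 1 / sqrt(2 * kappa[pos])
  out
}

#' Sample one step direction from the local fiber populations
#'
#' A population at `voxel` is eligible when its volume fraction is at
#' least `min_fraction` and — when an incoming direction exists — its
#' sign-aligned mean direction lies within the curvature threshold of the
#' incoming direction (this is what lets a streamline transit a crossing
#' region along its own fiber population instead of being captured or
#' killed by the transverse one). One eligible population is chosen with
#' probability proportional to its fraction; its mean direction is
#' perturbed by a Watson-like dispersion draw (isotropic Gaussian of sd
#' `1/sqrt(2*kappa)`, renormalised), and the sign is flipped so the dot
#' product with the incoming direction is nonnegative (fiber orientations
#' are axial, not polar). Termination is signalled when no population
#' passes the fraction test (`"low-fraction"`), when none passes the
#' curvature test, or when the perturbed draw itself exceeds the
#' curvature threshold (`"curvature"`).
#'
#' @param field An [orientation_field()].
#' @param voxel A 0-based voxel index triple.
#' @param incoming Incoming unit direction, or `NULL` at a streamline's
#'   first step (no sign alignment, no curvature check).
#' @param min_fraction,curvature_thresh See [tracking_params()].
#' @return A unit 3-vector, or a character termination signal
#'   (`"low-fraction"` / `"curvature"`).
#' @export
sample_step_direction <- function(field, voxel, incoming = NULL,
                                  min_fraction = 0.05,
                                  curvature_thresh = 80) {
  stopifnot(inherits(field, "orientation_field"))
  vox <- matrix(as.numeric(voxel), 1L)
  stopifnot(in_grid(vox, field$dim))
  lin <- voxel_linear(vox, field$dim)
  nvox <- prod(field$dim)
  f <- c(field$f1[lin], field$f2[lin])
  elig <- f >= min_fraction
  if (!any(elig)) {
    return("low-fraction")
  }
  cos_thresh <- cos(curvature_thresh * pi / 180)
  if (!is.null(incoming)) {
    mu1 <- c(field$dir1[lin], field$dir1[lin + nvox], field$dir1[lin + 2L * nvox])
    mu2 <- c(field$dir2[lin], field$dir2[lin + nvox], field$dir2[lin + 2L * nvox])
    elig <- elig & c(
      abs(sum(mu1 * incoming)) >= cos_thresh,
      abs(sum(mu2 * incoming)) >= cos_thresh
    )
    if (!any(elig)) {
      return("curvature")
    }
  }
  pick <- if (all(elig)) {
    if (stats::runif(1) < f[1] / sum(f)) 1L else 2L
  } else {
    which(elig)
  }
  darr <- if (pick == 1L) field$dir1 else field$dir2
  mu <- c(darr[lin], darr[lin + nvox], darr[lin + 2L * nvox])
  kap <- if (pick == 1L) field$kappa1[lin] else field$kappa2[lin]
  sd <- kappa_sd(kap)
  d <- mu + if (sd > 0) stats::rnorm(3L, 0, sd) else 0
  d <- d / sqrt(sum(d^2))
  if (!is.null(incoming)) {
    dp <- sum(d * incoming)
    if (dp < 0) {
      d <- -d
      dp <- -dp
    }
    if (acos(pmin(1, dp)) * 180 / pi > curvature_thresh) {
      return("curvature")
    }
  }
  d
}

# Vectorised half-streamline propagation. `start` is an n x 3 matrix of
# continuous voxel coordinates; `incoming` an n x 3 matrix of unit
# directions or NULL (free first step). Consumes the current R RNG stream.
# Returns visited voxel (id, lin) pairs including the start voxel,
# termination reasons, retention flags against `target_lin` (logical over
# linear indices, or NULL), the first sampled direction per streamline and
# (optionally) the full point lists.
track_half <- function(flat, start, incoming, params, target_lin = NULL,
                       record_points = FALSE) {
  n <- nrow(start)
  dim3 <- flat$dim
  pos <- start
  dir_in <- if (is.null(incoming)) matrix(NA_real_, n, 3L) else incoming
  active <- rep(TRUE, n)
  term <- rep(NA_character_, n)
  retained <- rep(FALSE, n)
  first_dir <- matrix(NA_real_, n, 3L)
  visits <- vector("list", params$max_steps + 1L)
  pts <- if (record_points) lapply(seq_len(n), function(i) list(start[i, ])) else NULL
  cos_thresh <- cos(params$curvature_thresh * pi / 180)

  vox0 <- floor(pos)
  ok0 <- in_grid(vox0, dim3)
  term[!ok0] <- "left-volume"
  active[!ok0] <- FALSE
  lin0 <- rep(NA_integer_, n)
  lin0[ok0] <- voxel_linear(vox0[ok0, , drop = FALSE], dim3)
  visits[[1L]] <- cbind(id = which(ok0), lin = lin0[ok0])
  if (!is.null(target_lin)) {
    hit0 <- ok0 & target_lin[pmax(lin0, 1L)] & !is.na(lin0)
    retained[hit0] <- TRUE
    term[hit0] <- "reached-target"
    active[hit0] <- FALSE
  }

  cur_lin <- lin0
  for (step in seq_len(params$max_steps)) {
    ids <- which(active)
    if (!length(ids)) break
    m <- length(ids)
    lin <- cur_lin[ids]
    f1 <- flat$f1[lin]
    f2 <- flat$f2[lin]
    e1 <- f1 >= params$min_fraction
    e2 <- f2 >= params$min_fraction
    lowf <- !e1 & !e2
    if (any(lowf)) {
      term[ids[lowf]] <- "low-fraction"
      active[ids[lowf]] <- FALSE
    }
    # curvature-aware eligibility: populations whose axial direction is
    # incompatible with the incoming direction are excluded from the draw
    inc_all <- dir_in[ids, , drop = FALSE]
    has_inc_all <- !is.na(inc_all[, 1L])
    if (any(has_inc_all)) {
      dp1 <- abs(rowSums(
        cbind(flat$D1[lin, 1L], flat$D1[lin, 2L], flat$D1[lin, 3L]) * inc_all
      ))
      dp2 <- abs(rowSums(
        cbind(flat$D2[lin, 1L], flat$D2[lin, 2L], flat$D2[lin, 3L]) * inc_all
      ))
      e1 <- e1 & (!has_inc_all | dp1 >= cos_thresh)
      e2 <- e2 & (!has_inc_all | dp2 >= cos_thresh)
      curv_dead <- !lowf & !e1 & !e2
      if (any(curv_dead)) {
        term[ids[curv_dead]] <- "curvature"
        active[ids[curv_dead]] <- FALSE
      }
    }
    live <- e1 | e2
    if (!any(live)) next
    idl <- ids[live]
    lin <- lin[live]
    f1 <- f1[live]
    f2 <- f2[live]
    e1 <- e1[live]
    e2 <- e2[live]
    m <- length(idl)

    p1 <- ifelse(e1 & e2, f1 / (f1 + f2), as.numeric(e1))
    pick1 <- stats::runif(m) < p1
    mu <- matrix(0, m, 3L)
    kap <- numeric(m)
    if (any(pick1)) {
      l1 <- lin[pick1]
      mu[pick1, ] <- cbind(flat$D1[l1, 1L], flat$D1[l1, 2L], flat$D1[l1, 3L])
      kap[pick1] <- flat$k1[l1]
    }
    if (any(!pick1)) {
      l2 <- lin[!pick1]
      mu[!pick1, ] <- cbind(flat$D2[l2, 1L], flat$D2[l2, 2L], flat$D2[l2, 3L])
      kap[!pick1] <- flat$k2[l2]
    }
    sdv <- kappa_sd(kap)
    d <- mu + matrix(stats::rnorm(3L * m), m, 3L) * sdv
    d <- unit_rows(d)

    inc <- dir_in[idl, , drop = FALSE]
    has_inc <- !is.na(inc[, 1L])
    ok <- rep(TRUE, m)
    if (any(has_inc)) {
      dp <- rowSums(d * inc)
      dp[!has_inc] <- 1
      flip <- has_inc & dp < 0
      d[flip, ] <- -d[flip, , drop = FALSE]
      dp <- abs(dp)
      curv <- has_inc & dp < cos_thresh
      if (any(curv)) {
        term[idl[curv]] <- "curvature"
        active[idl[curv]] <- FALSE
        ok <- !curv
      }
    }
    newfirst <- is.na(first_dir[idl, 1L]) & ok
    if (any(newfirst)) {
      first_dir[idl[newfirst], ] <- d[newfirst, , drop = FALSE]
    }
    if (!any(ok)) next
    ido <- idl[ok]
    newpos <- pos[ido, , drop = FALSE] + params$step_size * d[ok, , drop = FALSE]
    vox <- floor(newpos)
    inb <- in_grid(vox, dim3)
    if (any(!inb)) {
      term[ido[!inb]] <- "left-volume"
      active[ido[!inb]] <- FALSE
    }
    idk <- ido[inb]
    if (!length(idk)) next
    newpos <- newpos[inb, , drop = FALSE]
    linn <- voxel_linear(vox[inb, , drop = FALSE], dim3)
    pos[idk, ] <- newpos
    cur_lin[idk] <- linn
    dir_in[idk, ] <- d[ok, , drop = FALSE][inb, , drop = FALSE]
    visits[[step + 1L]] <- cbind(id = idk, lin = linn)
    if (record_points) {
      for (q in seq_along(idk)) {
        pts[[idk[q]]][[length(pts[[idk[q]]]) + 1L]] <- newpos[q, ]
      }
    }
    if (!is.null(target_lin)) {
      hit <- target_lin[linn]
      if (any(hit)) {
        retained[idk[hit]] <- TRUE
        term[idk[hit]] <- "reached-target"
        active[idk[hit]] <- FALSE
      }
    }
  }
  term[active] <- "max-steps"
  list(
    visits = do.call(rbind, visits[!vapply(visits, is.null, logical(1))]),
    term = term, retained = retained, first_dir = first_dir,
    points = if (record_points) {
      lapply(pts, function(p) do.call(rbind, p))
    } else {
      NULL
    }
  )
}

#' Propagate a single probabilistic streamline
#'
#' Euler stepping: at the current voxel a direction is sampled from the
#' local fiber populations (see [sample_step_direction()]) and the point
#' advances by the step size. Tracking runs in both directions from the
#' start point — the second half starts with the negated first direction
#' of the first half — and the two halves are concatenated.
#'
#' @param field An [orientation_field()].
#' @param start Continuous voxel-space start point (length 3).
#' @param params A [tracking_params()].
#' @return A list of class `streamline`: `points` (n x 3 matrix of
#'   continuous voxel coordinates, backward half reversed then forward
#'   half), and `termination` (named character of length 2: the reason
#'   each half stopped, one of `reached-target`, `left-volume`,
#'   `low-fraction`, `curvature`, `max-steps`).
#' @export
propagate_streamline <- function(field, start, params = tracking_params()) {
  flat <- flatten_field(field)
  start <- matrix(as.numeric(start), 1L)
  fwd <- track_half(flat, start, NULL, params, record_points = TRUE)
  if (!is.na(fwd$first_dir[1L, 1L])) {
    bwd <- track_half(flat, start, -fwd$first_dir, params,
      record_points = TRUE
    )
    bpts <- bwd$points[[1L]]
    pts <- rbind(bpts[rev(seq_len(nrow(bpts))[-1L]), , drop = FALSE],
      fwd$points[[1L]]
    )
    termb <- bwd$term[1L]
  } else {
    pts <- fwd$points[[1L]]
    termb <- fwd$term[1L]
  }
  structure(
    list(
      points = pts,
      termination = c(forward = fwd$term[1L], backward = termb)
    ),
    class = "streamline"
  )
}

#' Track one seed-to-target pathway
#'
#' Launches `n_per_seed` bidirectional streamlines from the centre of every
#' seed voxel. A streamline is retained iff it enters the target mask (in
#' either propagation direction); it is truncated at target entry, so
#' voxels past the target do not contribute. The visitation map counts,
#' per voxel, the retained streamlines that pass through it (each retained
#' streamline contributes at most 1 per voxel); the binary pathway mask
#' thresholds that map at `mask_threshold`.
#'
#' @param field An [orientation_field()].
#' @param seed_voxels n x 3 integer matrix of 0-based seed voxel indices
#'   (must be nonempty).
#' @param target_mask 3D logical array marking the target ROI.
#' @param params A [tracking_params()].
#' @param seed RNG seed for this task (derive one per task from the master
#'   seed with [derive_seed()] so tasks are order-independent).
#' @param seed_name,target_name Labels carried into the result.
#' @return An object of class `pathway_result`: `visit_count` (3D integer
#'   array), `n_retained`, `n_streamlines`, `mask` (3D logical),
#'   `n_voxels` (true mask voxels), plus the labels and parameters.
#' @export
track_pathway <- function(field, seed_voxels, target_mask,
                          params = tracking_params(), seed = params$seed,
                          seed_name = "seed", target_name = "target") {
  stopifnot(inherits(field, "orientation_field"))
  seed_voxels <- as_points(seed_voxels)
  if (nrow(seed_voxels) == 0L) {
    stop("seed voxel set is empty", call. = FALSE)
  }
  stopifnot(identical(dim(target_mask), field$dim))
  flat <- flatten_field(field)
  target_lin <- as.vector(target_mask)

  starts <- seed_voxels[rep(seq_len(nrow(seed_voxels)),
    each = params$n_per_seed
  ), , drop = FALSE] + 0.5
  n <- nrow(starts)
  set.seed(derive_seed(seed, "track", seed_name, target_name))
  fwd <- track_half(flat, starts, NULL, params, target_lin)
  bwd <- track_half(flat, starts, -fwd$first_dir, params, target_lin)
  retained <- fwd$retained | bwd$retained

  visit_count <- integer(prod(field$dim))
  if (any(retained)) {
    vis <- rbind(fwd$visits, bwd$visits)
    vis <- vis[retained[vis[, "id"]], , drop = FALSE]
    vis <- vis[!duplicated(vis), , drop = FALSE]
    tab <- tabulate(vis[, "lin"], nbins = prod(field$dim))
    visit_count <- as.integer(tab)
  }
  visit_count <- array(visit_count, field$dim)
  mask <- visit_count >= params$mask_threshold
  structure(
    list(
      seed_name = seed_name, target_name = target_name,
      visit_count = visit_count, mask = mask,
      n_voxels = sum(mask), n_retained = sum(retained),
      n_streamlines = n, params = params, affine = field$affine
    ),
    class = "pathway_result"
  )
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(
    "<pathway_result> ", x$seed_name, " -> ", x$target_name, ": ",
    x$n_retained, "/", x$n_streamlines, " streamlines retained, ",
    x$n_voxels, " pathway voxels\n",
    sep = ""
  )
  invisible(x)
}

#' Re-threshold a visitation map into a pathway mask
#'
#' @param result A [track_pathway()] result.
#' @param mask_threshold New minimum visitation count.
#' @return The result with `mask` and `n_voxels` recomputed.
#' @export
rethreshold_mask <- function(result, mask_threshold) {
  stopifnot(inherits(result, "pathway_result"), mask_threshold > 0)
  result$mask <- result$visit_count >= mask_threshold
  result$n_voxels <- sum(result$mask)
  result$params$mask_threshold <- as.integer(mask_threshold)
  result
}

#' Enumerate hemisphere-matched seed-to-target tracking tasks
#'
#' One task is produced per hemisphere per bilateral target structure:
#' left seed to left target and right seed to right target. Midline
#' structures cannot be hemisphere-matched and are excluded (with a
#' message); with one bilateral seed and six bilateral targets this yields
#' 2 x 1 x 6 = 12 tasks.
#'
#' @param registry An [roi_registry()].
#' @param seed_name Name of the (bilateral) seed structure.
#' @param target_names Names of target structures.
#' @return A tibble with columns `task_id`, `hemisphere`, `seed_name`,
#'   `seed_label`, `target_name`, `target_label`.
#' @export
#' @examples
#' enumerate_pathway_tasks(
#'   default_roi_registry(), "hippocampus",
#'   c(
#'     "nucleus_accumbens", "amygdala", "caudate_nucleus",
#'     "globus_pallidus", "putamen", "thalamus"
#'   )
#' )
enumerate_pathway_tasks <- function(registry, seed_name, target_names) {
  unknown <- setdiff(c(seed_name, target_names), registry$name)
  if (length(unknown)) {
    stop("unknown structure(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  seed_hemis <- registry$hemisphere[registry$name == seed_name]
  if (!setequal(seed_hemis, c("left", "right"))) {
    stop(sprintf("seed structure '%s' is not bilateral", seed_name),
      call. = FALSE
    )
  }
  rows <- list()
  for (tg in target_names) {
    hemis <- registry$hemisphere[registry$name == tg]
    if (identical(hemis, "midline")) {
      message(sprintf("midline structure '%s' excluded from tasks", tg))
      next
    }
    for (hemi in intersect(c("left", "right"), hemis)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        task_id = paste(hemi, seed_name, tg, sep = "_"),
        hemisphere = hemi,
        seed_name = seed_name,
        seed_label = roi_label(registry, seed_name, hemi),
        target_name = tg,
        target_label = roi_label(registry, tg, hemi)
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      task_id = character(), hemisphere = character(),
      seed_name = character(), seed_label = integer(),
      target_name = character(), target_label = integer()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$target_name, .data$hemisphere)
}
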