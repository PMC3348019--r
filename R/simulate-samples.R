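#' Scatter expression samples across a phantom
#'
#' Places `n_samples` samples in the phantom's bounding box, forcing a
#' configurable share of them inside each fiber tract tube and scattering
#' the rest uniformly. Every sample carries ground-truth in-tube flags,
#' computed geometrically (distance to the dense centerline at most the
#' tube radius), so downstream selection stages can be checked against
#' construction.
#'
#' @param phantom A [make_phantom()] result.
#' @param n_samples Total number of samples (>= 1).
#' @param in_tube Either a single fraction in `[0, 1]` (that share of
#'   samples is forced in-tube, split evenly over tracts) or a named
#'   integer vector of forced counts per `tract_id`.
#' @param seed RNG seed.
#' @return A tibble with columns `sample_id`, `x`, `y`, `z` (world mm) and
#'   one logical ground-truth column `in_<tract_id>` per tract.
#' @export
#' @examples
#' ph <- make_phantom(default_phantom_config())
#' make_samples(ph, n_samples = 20, seed = 1)
make_samples <- function(phantom, n_samples = 200L, in_tube = 0.5, seed = 0L) {
  stopifnot(inherits(phantom, "fiberlink_phantom"))
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  tracts <- phantom$config$tracts
  if (is.null(names(in_tube))) {
    stopifnot(length(in_tube) == 1L, in_tube >= 0, in_tube <= 1)
    n_forced_total <- round(in_tube * n_samples)
    n_tr <- nrow(tracts)
    forced <- if (n_tr > 0L) {
      base <- n_forced_total %/% n_tr
      extra <- n_forced_total %% n_tr
      stats::setNames(base + (seq_len(n_tr) <= extra), tracts$tract_id)
    } else {
      integer()
    }
  } else {
    bad <- setdiff(names(in_tube), tracts$tract_id)
    if (length(bad)) {
      stop("unknown tract id(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    forced <- in_tube
  }
  if (sum(forced) > n_samples) {
    stop("forced in-tube counts exceed n_samples", call. = FALSE)
  }

  set.seed(derive_seed(seed, "samples"))
  dim3 <- phantom$config$grid_shape
  pts <- matrix(NA_real_, 0L, 3L)
  for (tid in names(forced)) {
    k <- forced[[tid]]
    if (k == 0L) next
    tr <- tracts[tracts$tract_id == tid, ]
    cl <- phantom$centerlines[[tid]]
    pick <- sample.int(nrow(cl$points), k, replace = TRUE)
    # uniform draws in a ball of 0.9 * tube radius around a centerline point
    offs <- matrix(stats::rnorm(3L * k), k, 3L)
    offs <- unit_rows(offs) * (0.9 * tr$radius * stats::runif(k)^(1 / 3))
    pts <- rbind(pts, cl$points[pick, , drop = FALSE] + offs)
  }
  n_free <- n_samples - nrow(pts)
  if (n_free > 0L) {
    free <- cbind(
      stats::runif(n_free, 0, dim3[1]),
      stats::runif(n_free, 0, dim3[2]),
      stats::runif(n_free, 0, dim3[3])
    )
    pts <- rbind(pts, free)
  }

  world <- apply_affine(unclass(phantom$affine), pts)
  out <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    x = world[, 1], y = world[, 2], z = world[, 3]
  )
  for (t in seq_len(nrow(tracts))) {
    tid <- tracts$tract_id[t]
    d <- distance_to_tract(phantom, pts, tid)
    out[[paste0("in_", tid)]] <- d <= tracts$radius[t]
  }
  out
}

#' Simulate a probe-by-sample log2 expression matrix
#'
#' Per-probe baseline intensities are drawn from a normal distribution
#' (default mean 7, sd 1 across probes, a typical microarray log2 scale);
#' per-sample measurement noise is normal with `noise_sd`. Every probe of
#' a planted gene receives an additional `+delta` log2 units for exactly
#' the samples whose ground-truth flag marks them inside the planted
#' pathway's tube.
#'
#' @param samples A [make_samples()] tibble.
#' @param probe_gene_map Tibble with columns `probe_id`, `gene_id`.
#' @param planted Tibble with columns `gene_id`, `tract_id`, `delta`
#'   (log2 units, > 0); may have zero rows.
#' @param noise_sd Per-measurement noise standard deviation.
#' @param baseline_mean,baseline_sd Parameters of the per-probe baseline.
#' @param seed RNG seed.
#' @return A numeric matrix (probes x samples) with dimnames.
#' @export
make_expression <- function(samples, probe_gene_map, planted = NULL,
                            noise_sd = 0.5, baseline_mean = 7,
                            baseline_sd = 1, seed = 0L) {
  if (is.null(planted)) {
    planted <- tibble::tibble(
      gene_id = character(), tract_id = character(), delta = numeric()
    )
  }
  missing <- setdiff(planted$gene_id, probe_gene_map$gene_id)
  if (length(missing)) {
    stop(
      "planted gene(s) with no probe: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  n_p <- nrow(probe_gene_map)
  n_s <- nrow(samples)
  set.seed(derive_seed(seed, "expression"))
  baseline <- stats::rnorm(n_p, baseline_mean, baseline_sd)
  x <- baseline + matrix(stats::rnorm(n_p * n_s, 0, noise_sd), n_p, n_s)
  dimnames(x) <- list(probe_gene_map$probe_id, samples$sample_id)
  for (p in seq_len(nrow(planted))) {
    col <- paste0("in_", planted$tract_id[p])
    if (!col %in% names(samples)) {
      stop(sprintf(
        "planted pathway '%s' not among the sample ground-truth flags",
        planted$tract_id[p]
      ), call. = FALSE)
    }
    rows <- which(probe_gene_map$gene_id == planted$gene_id[p])
    cols <- which(samples[[col]])
    if (length(rows) && length(cols)) {
      x[rows, cols] <- x[rows, cols] + planted$delta[p]
    }
  }
  x
}

#' Generate a probe/gene annotation for synthetic runs
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Probes per gene.
#' @return A list with `probe_gene_map` (tibble: probe_id, gene_id) and
#'   `genes` (character vector of gene ids).
#' @export
make_gene_annotation <- function(n_genes = 60L, probes_per_gene = 2L) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  map <- tidyr::expand_grid(gene_id = genes, p = seq_len(probes_per_gene))
  map <- dplyr::mutate(map,
    probe_id = sprintf("%s_p%d", .data$gene_id, .data$p)
  )
  list(
    probe_gene_map = dplyr::select(map, "probe_id", "gene_id"),
    genes = genes
  )
}
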