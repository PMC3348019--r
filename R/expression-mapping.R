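#' Select expression samples located inside a pathway mask
#'
#' A sample is selected iff its world coordinate maps to an in-bounds
#' voxel (floor convention, see [world_to_voxel()]) at which the mask is
#' true. Out-of-bounds samples are excluded and counted in a warning; the
#' count is also attached as attribute `n_out_of_bounds`.
#'
#' @param samples A sample tibble with columns `sample_id`, `x`, `y`, `z`
#'   (world mm); ids must be unique.
#' @param mask 3D logical pathway mask.
#' @param affine The [affine_transform()] of the mask volume.
#' @return The subset of `samples` inside the mask, same columns.
#' @export
samples_in_pathway <- function(samples, mask, affine) {
  stopifnot(
    all(c("sample_id", "x", "y", "z") %in% names(samples)),
    !anyDuplicated(samples$sample_id)
  )
  if (nrow(samples) == 0L) {
    out <- samples
    attr(out, "n_out_of_bounds") <- 0L
    return(out)
  }
  vox <- world_to_voxel(affine, as.matrix(samples[, c("x", "y", "z")]),
    dim = dim(mask)
  )
  oob <- is.na(vox[, 1L])
  warn_count(sum(oob), "sample(s) outside the volume excluded")
  inside <- rep(FALSE, nrow(samples))
  if (any(!oob)) {
    lin <- voxel_linear(vox[!oob, , drop = FALSE], dim(mask))
    inside[!oob] <- as.vector(mask)[lin]
  }
  out <- samples[inside, , drop = FALSE]
  attr(out, "n_out_of_bounds") <- sum(oob)
  out
}

#' Per-probe z-score normalization
#'
#' For each probe, the mean `mu` and standard deviation `sigma` are
#' computed across *all* samples of the matrix (whole-brain reference by
#' default — normalization happens before any pathway selection) and each
#' intensity is standardised as `z = (x - mu) / sigma`. The population
#' (divide-by-n) convention is the default; `sd = "sample"` switches to
#' divide-by-(n-1). Probes with `sigma = 0` yield missing z-scores and a
#' warning, never a division error.
#'
#' @param x Probes-by-samples numeric matrix of log2 intensities, with
#'   dimnames.
#' @param sd `"population"` (default) or `"sample"`.
#' @return A list of class `probe_zscores`: `z` (same shape as `x`) and
#'   `stats` (tibble: `probe_id`, `mu`, `sigma`).
#' @export
#' @examples
#' m <- rbind(p1 = c(6, 8), p2 = c(1, 3))
#' colnames(m) <- c("s1", "s2")
#' probe_zscores(m)$z
probe_zscores <- function(x, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  stopifnot(is.matrix(x), is.numeric(x), all(is.finite(x)))
  n <- ncol(x)
  if (n < 2L) stop("z-scores need >= 2 samples", call. = FALSE)
  mu <- rowMeans(x)
  dev <- x - mu
  denom <- if (sd == "population") n else n - 1L
  sigma <- sqrt(rowSums(dev^2) / denom)
  z <- dev / sigma
  const <- sigma == 0
  if (any(const)) {
    z[const, ] <- NA_real_
    warn_count(sum(const), "constant probe(s): z-scores set to missing")
  }
  structure(
    list(
      z = z,
      stats = tibble::tibble(
        probe_id = rownames(x) %||% as.character(seq_len(nrow(x))),
        mu = unname(mu), sigma = unname(sigma)
      ),
      sd_convention = sd
    ),
    class = "probe_zscores"
  )
}

#' @export
print.probe_zscores <- function(x, ...) {
  cat(
    "<probe_zscores> ", nrow(x$z), " probes x ", ncol(x$z), " samples (",
    x$sd_convention, " sd)\n",
    sep = ""
  )
  invisible(x)
}

#' Aggregate probe z-scores to gene level
#'
#' The gene-level z-score of a sample is the arithmetic mean of that
#' gene's probe z-scores at the sample, skipping missing values; a
#' gene-sample cell is missing iff all of its probes are missing there.
#'
#' @param z A [probe_zscores()] result or a probes-by-samples z matrix.
#' @param probe_gene_map Tibble with columns `probe_id`, `gene_id`.
#' @param genes Genes to aggregate; every one must have at least one probe
#'   present in `z` (a hard error lists offenders otherwise).
#' @return A genes-by-samples numeric matrix.
#' @export
gene_zscores <- function(z, probe_gene_map, genes) {
  if (inherits(z, "probe_zscores")) z <- z$z
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  map <- probe_gene_map[probe_gene_map$probe_id %in% rownames(z), ]
  have <- unique(map$gene_id)
  missing <- setdiff(genes, have)
  if (length(missing)) {
    stop(
      "gene(s) with no probe in the matrix: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- matrix(NA_real_, length(genes), ncol(z),
    dimnames = list(genes, colnames(z))
  )
  for (g in genes) {
    probes <- map$probe_id[map$gene_id == g]
    sub <- z[probes, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[colSums(!is.na(sub)) == 0L] <- NA_real_
    out[g, ] <- m
  }
  out
}

#' Per-pathway average z-scores
#'
#' For each gene, the average z-score over the selected samples with
#' non-missing values; `n` records how many samples contributed. Genes
#' with `n = 0` are omitted with a warning; an empty selection yields a
#' zero-row summary plus a warning (pathways can legitimately contain no
#' samples).
#'
#' @param gene_z Genes-by-samples z matrix from [gene_zscores()].
#' @param sample_ids Ids of the samples selected for the pathway.
#' @param pathway Label recorded in the output.
#' @return A tibble of class `pathway_gene_summary` with columns
#'   `pathway`, `gene_id`, `avg_z`, `n` and a list column `sample_ids`.
#' @export
pathway_average <- function(gene_z, sample_ids, pathway = "pathway") {
  stopifnot(is.matrix(gene_z), !is.null(colnames(gene_z)))
  unknown <- setdiff(sample_ids, colnames(gene_z))
  if (length(unknown)) {
    stop("sample id(s) absent from the z matrix: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  empty <- tibble::tibble(
    pathway = character(), gene_id = character(),
    avg_z = numeric(), n = integer(), sample_ids = list()
  )
  if (length(sample_ids) == 0L) {
    warning(sprintf("pathway '%s': no samples selected", pathway),
      call. = FALSE
    )
    return(structure(empty, class = c("pathway_gene_summary", class(empty))))
  }
  sub <- gene_z[, sample_ids, drop = FALSE]
  n <- rowSums(!is.na(sub))
  avg <- rowSums(sub, na.rm = TRUE) / n
  warn_count(sum(n == 0L), "gene(s) with no usable z-score omitted")
  keep <- n > 0L
  out <- tibble::tibble(
    pathway = pathway,
    gene_id = rownames(sub)[keep],
    avg_z = unname(avg[keep]),
    n = as.integer(unname(n[keep])),
    sample_ids = lapply(which(keep), function(g) {
      sample_ids[!is.na(sub[g, ])]
    })
  )
  structure(out, class = c("pathway_gene_summary", class(empty)))
}
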