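#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pathway result into a per-voxel tibble
#'
#' One row per voxel visited by at least one retained streamline, with its
#' 0-based index, visitation count and mask membership.
#'
#' @param x A [track_pathway()] result.
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, `k`, `count`, `in_mask`.
#' @method tidy pathway_result
#' @export
tidy.pathway_result <- function(x, ...) {
  idx <- which(x$visit_count > 0L, arr.ind = TRUE)
  tibble::tibble(
    i = idx[, 1L] - 1L, j = idx[, 2L] - 1L, k = idx[, 3L] - 1L,
    count = x$visit_count[idx],
    in_mask = x$mask[idx]
  )
}

#' @rdname tidy.pathway_result
#' @method glance pathway_result
#' @export
glance.pathway_result <- function(x, ...) {
  tibble::tibble(
    seed = x$seed_name, target = x$target_name,
    n_streamlines = x$n_streamlines, n_retained = x$n_retained,
    retained_frac = x$n_retained / x$n_streamlines,
    n_voxels = x$n_voxels,
    mask_threshold = x$params$mask_threshold
  )
}

#' Tidy and summarise a tier assignment
#'
#' `tidy()` returns the node-level table (protein, tier, k); `glance()`
#' one row of tier counts.
#'
#' @param x A [classify_nodes()] result.
#' @param ... Unused.
#' @method tidy tier_assignment
#' @export
tidy.tier_assignment <- function(x, ...) {
  tibble::tibble(
    protein = x$protein, tier = x$tier, k = x$k
  )
}

#' @rdname tidy.tier_assignment
#' @method glance tier_assignment
#' @export
glance.tier_assignment <- function(x, ...) {
  counts <- table(x$tier)
  out <- tibble::as_tibble(as.list(counts))
  out$n_nodes <- nrow(x)
  out
}

#' Glance at a full report bundle
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return One summary row: task counts, nonempty pathways, sample and
#'   gene totals, filtered-gene and tiered-node counts.
#' @method glance report_bundle
#' @export
glance.report_bundle <- function(x, ...) {
  tibble::tibble(
    n_tasks = nrow(x$pathway_table),
    n_nonempty = sum(x$pathway_table$n_voxels > 0L),
    n_retained_total = sum(x$pathway_table$n_retained),
    n_samples_in_pathways = sum(x$pathway_table$n_samples),
    n_disease_genes = nrow(x$interaction_table),
    n_filtered_genes = nrow(x$filtered_genes),
    n_tiered_nodes = nrow(x$tiers)
  )
}
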