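#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pathway visitation map
#'
#' Maximum-intensity projection of the visitation count map along one
#' axis, with mask voxels outlined by projection as well.
#'
#' @param object A [track_pathway()] result.
#' @param axis Projection axis: 1 (sagittal), 2 (coronal) or 3 (axial).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pathway_result
#' @export
autoplot.pathway_result <- function(object, axis = 3L, ...) {
  proj <- apply(object$visit_count, setdiff(1:3, axis), max)
  mask_proj <- apply(object$mask, setdiff(1:3, axis), any)
  ax <- c("i", "j", "k")[setdiff(1:3, axis)]
  df <- tidyr::expand_grid(
    a = seq_len(nrow(proj)) - 1L, b = seq_len(ncol(proj)) - 1L
  )
  df$count <- as.vector(proj)
  df$in_mask <- as.vector(mask_proj)
  ggplot2::ggplot(
    df[df$count > 0L, ],
    ggplot2::aes(x = .data$a, y = .data$b, fill = .data$count)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s → %s", object$seed_name, object$target_name),
      subtitle = sprintf(
        "%d/%d streamlines retained, %d mask voxels",
        object$n_retained, object$n_streamlines, object$n_voxels
      ),
      x = ax[1L], y = ax[2L], fill = "visits"
    )
}

#' Boxplots of per-pathway gene z-scores
#'
#' The long-format analogue of the per-pathway expression figures: one box
#' per pathway over its genes' average z-scores.
#'
#' @param gene_summary A long summary tibble (rows = pathway x gene), as
#'   produced by [pathway_average()] / [run_pipeline()].
#' @return A ggplot.
#' @export
plot_pathway_zscores <- function(gene_summary) {
  stopifnot(all(c("pathway", "avg_z") %in% names(gene_summary)))
  ggplot2::ggplot(
    gene_summary,
    ggplot2::aes(x = .data$pathway, y = .data$avg_z)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "average z-score")
}

#' Plot a tiered PPI subnetwork
#'
#' Fruchterman-Reingold layout of the induced subnetwork with nodes
#' coloured by tier (seed, related, tier3plus, tier2, peripheral).
#'
#' @param object A [classify_nodes()] result.
#' @param seed Layout RNG seed (layouts are stochastic).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tier_assignment
#' @export
autoplot.tier_assignment <- function(object, seed = 1L, ...) {
  g <- attr(object, "subgraph")
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    protein = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L]
  )
  nodes <- dplyr::left_join(
    nodes, tibble::as_tibble(object)[, c("protein", "tier")],
    by = "protein"
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1L], nodes$protein)],
    y = nodes$y[match(el[, 1L], nodes$protein)],
    xend = nodes$x[match(el[, 2L], nodes$protein)],
    yend = nodes$y[match(el[, 2L], nodes$protein)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend
      ),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$tier),
      size = 3
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "tier")
}
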