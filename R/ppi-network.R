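#' Build an undirected, deduplicated PPI graph from an edge list
#'
#' Duplicate edges (including reversed duplicates) are collapsed and
#' self-loops are dropped with a counted warning. Malformed rows (missing
#' or empty protein ids) are a hard error reporting the offending row
#' numbers.
#'
#' @param edges A two-column data frame (or tibble) of protein-id pairs;
#'   extra columns are ignored.
#' @return An undirected simple [igraph::graph] over the protein ids.
#' @export
#' @examples
#' g <- build_ppi_graph(tibble::tibble(
#'   a = c("A", "B", "A"), b = c("B", "A", "A")
#' ))
build_ppi_graph <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edge list needs two columns", call. = FALSE)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad)) {
    stop(
      "malformed edge row(s): ",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) " ..." else "",
      call. = FALSE
    )
  }
  loops <- a == b
  warn_count(sum(loops), "self-loop(s) dropped")
  a2 <- pmin(a[!loops], b[!loops])
  b2 <- pmax(a[!loops], b[!loops])
  keep <- !duplicated(paste(a2, b2, sep = "\r"))
  igraph::graph_from_data_frame(
    data.frame(from = a2[keep], to = b2[keep]),
    directed = FALSE
  )
}

graph_neighbors <- function(graph, protein) {
  names(igraph::neighbors(graph, protein))
}

#' Count unique interaction partners for disease genes
#'
#' Maps each disease gene to its protein and counts the protein's unique
#' interaction partners in the graph (self-interactions excluded; the
#' graph is already simple). Genes without a protein mapping, and genes
#' whose protein is absent from the graph, are reported separately rather
#' than silently dropped.
#'
#' @param graph A [build_ppi_graph()] result.
#' @param disease_genes Character vector of gene ids.
#' @param gene_protein_map Tibble with columns `gene_id`, `protein_id`.
#' @return A tibble (`gene_id`, `protein_id`, `n_ppi`), one row per mapped
#'   gene in input order; attribute `unmapped` lists genes without a
#'   protein mapping.
#' @export
interaction_counts <- function(graph, disease_genes, gene_protein_map) {
  map <- gene_protein_map[match(disease_genes, gene_protein_map$gene_id), ]
  unmapped <- disease_genes[is.na(map$protein_id)]
  mapped <- !is.na(map$protein_id)
  prot <- map$protein_id[mapped]
  in_graph <- prot %in% igraph::V(graph)$name
  n_ppi <- integer(length(prot))
  n_ppi[in_graph] <- vapply(
    prot[in_graph],
    function(p) length(graph_neighbors(graph, p)),
    integer(1)
  )
  out <- tibble::tibble(
    gene_id = disease_genes[mapped],
    protein_id = prot,
    n_ppi = n_ppi
  )
  attr(out, "unmapped") <- unmapped
  out
}

#' Keep genes with strictly more than `min_count` interactions
#'
#' The filter is strict (`n_ppi > min_count`, so a gene with exactly
#' `min_count` partners is dropped) and preserves table order.
#'
#' @param counts An [interaction_counts()] table (columns `gene_id`,
#'   `n_ppi` required).
#' @param min_count Threshold (default 10).
#' @return The filtered tibble.
#' @export
filter_by_degree <- function(counts, min_count = 10L) {
  stopifnot(min_count >= 0, all(c("gene_id", "n_ppi") %in% names(counts)))
  counts[counts$n_ppi > min_count, , drop = FALSE]
}

#' Direct neighborhood of the seed protein
#'
#' Returns the seed's direct interaction partners, optionally intersected
#' with a curated restriction roster (the related set need not be purely
#' topological).
#'
#' @param graph A [build_ppi_graph()] result.
#' @param seed_protein Seed protein id (must be in the graph).
#' @param restrict Optional character vector to intersect with.
#' @return Character vector of related proteins.
#' @export
seed_related_set <- function(graph, seed_protein, restrict = NULL) {
  if (!seed_protein %in% igraph::V(graph)$name) {
    stop(sprintf("seed protein '%s' absent from graph", seed_protein),
      call. = FALSE
    )
  }
  nb <- graph_neighbors(graph, seed_protein)
  if (!is.null(restrict)) nb <- intersect(nb, restrict)
  nb
}

#' Tier classification of the seed neighborhood
#'
#' Writing `C = {seed} + related`, every node outside `C` that is adjacent
#' to at least one member of `C` is classified by `k(v)`, its number of
#' unique neighbors inside `C`: `tier3plus` when `k >= 3`, `tier2` when
#' `k = 2`, `peripheral` when `k = 1`. Nodes not adjacent to any member of
#' `C` are excluded from the subnetwork. Related-set members keep tier
#' `"related"` regardless of their own `k`, and the seed is its own tier.
#' With `rule = "exact3"`, `tier3plus` requires `k == 3` exactly and nodes
#' with `k >= 4` are labelled `"unclassified"`.
#'
#' @param graph A [build_ppi_graph()] result.
#' @param seed_protein Seed protein id.
#' @param related Character vector of related proteins (must be graph
#'   nodes).
#' @param rule `"at_least3"` (default) or `"exact3"`.
#' @return A tibble of class `tier_assignment` with columns `protein`,
#'   `tier` (factor: seed, related, tier3plus, tier2, peripheral,
#'   unclassified) and `k`; the induced subgraph is attached as attribute
#'   `subgraph`.
#' @export
classify_nodes <- function(graph, seed_protein, related,
                           rule = c("at_least3", "exact3")) {
  rule <- match.arg(rule)
  nodes <- igraph::V(graph)$name
  if (!all(c(seed_protein, related) %in% nodes)) {
    stop("seed and related proteins must all be graph nodes", call. = FALSE)
  }
  core <- union(seed_protein, related)
  k_of <- function(v) length(intersect(graph_neighbors(graph, v), core))
  outside <- setdiff(nodes, core)
  k_out <- vapply(outside, k_of, integer(1))
  member <- outside[k_out > 0L]
  k_member <- k_out[k_out > 0L]
  tier <- ifelse(
    k_member >= 3L,
    if (rule == "at_least3") "tier3plus" else NA,
    ifelse(k_member == 2L, "tier2", "peripheral")
  )
  if (rule == "exact3") {
    tier[k_member == 3L] <- "tier3plus"
    tier[k_member > 3L] <- "unclassified"
  }
  levels <- c(
    "seed", "related", "tier3plus", "tier2", "peripheral", "unclassified"
  )
  out <- tibble::tibble(
    protein = c(seed_protein, setdiff(related, seed_protein), member),
    tier = factor(
      c(
        "seed", rep("related", length(setdiff(related, seed_protein))),
        tier
      ),
      levels = levels
    ),
    k = c(
      vapply(seed_protein, k_of, integer(1)),
      vapply(setdiff(related, seed_protein), k_of, integer(1)),
      as.integer(k_member)
    )
  )
  attr(out, "subgraph") <- igraph::induced_subgraph(graph, out$protein)
  attr(out, "seed_protein") <- seed_protein
  class(out) <- c("tier_assignment", class(out))
  out
}

#' Extract the tiered subnetwork and its annotated edge table
#'
#' @param graph A [build_ppi_graph()] result.
#' @param tiers A [classify_nodes()] assignment.
#' @return A list: `subgraph` (induced [igraph::graph] on the tiered
#'   nodes) and `edges` (tibble `protein_a`, `protein_b`, `tier_a`,
#'   `tier_b`).
#' @export
extract_subnetwork <- function(graph, tiers) {
  stopifnot(inherits(tiers, "tier_assignment"))
  sub <- igraph::induced_subgraph(graph, tiers$protein)
  el <- igraph::as_edgelist(sub)
  lookup <- stats::setNames(as.character(tiers$tier), tiers$protein)
  edges <- tibble::tibble(
    protein_a = if (nrow(el)) el[, 1L] else character(),
    protein_b = if (nrow(el)) el[, 2L] else character()
  )
  edges$tier_a <- unname(lookup[edges$protein_a])
  edges$tier_b <- unname(lookup[edges$protein_b])
  list(subgraph = sub, edges = edges)
}

#' Bundled worked-example table: Alzheimer-related genes with many PPIs
#'
#' Loads the packaged table of 33 Alzheimer's-disease-related genes that
#' have more than 10 protein-protein interactions in HPRD, with their HPRD
#' identifiers and unique-partner interaction counts. Used by the worked
#' examples and acceptance checks as a printed-table input.
#'
#' @return A tibble with columns `index`, `gene_id`, `hprd_id`, `n_ppi`.
#' @export
alzheimer_ppi_table <- function() {
  path <- system.file("extdata", "alzheimer_gene_ppi.tsv",
    package = "fiberlink", mustWork = TRUE
  )
  readr::read_tsv(path, show_col_types = FALSE, col_types = "icci")
}
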