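#' Design a synthetic protein-protein interaction graph with known tiers
#'
#' Builds an undirected, deduplicated, self-loop-free edge list in which
#' the neighborhood structure around a designated seed protein is known by
#' construction. Writing `C = {seed} + related`, every designed tier-k
#' protein receives exactly `k` distinct partners inside `C` (k = 3 for
#' `tier3`, 2 for `tier2`, 1 for `peripheral`), the seed is connected to
#' every related protein, and any random extra edges are drawn strictly
#' among proteins outside `C`, so they can never change a designed tier.
#'
#' @param proteins Character vector of protein ids available for extra
#'   random edges (tier members and extras; the seed and related proteins
#'   are added automatically).
#' @param seed_protein The seed protein id.
#' @param tier_design A list with character-vector elements `related`,
#'   `tier3`, `tier2`, `peripheral`; the four sets must be disjoint and
#'   must not contain the seed.
#' @param n_extra_edges Number of random edges among non-`C` proteins.
#' @param seed RNG seed.
#' @return A list with `edges` (tibble: `protein_a`, `protein_b`),
#'   `gene_protein_map` (tibble: `gene_id`, `protein_id`; gene ids are the
#'   protein ids prefixed with `"g_"`) and the echoed `tier_design`.
#' @export
#' @examples
#' make_ppi(
#'   proteins = sprintf("X%02d", 1:8), seed_protein = "APPX",
#'   tier_design = list(
#'     related = c("R1", "R2", "R3"), tier3 = "T3a",
#'     tier2 = "T2a", peripheral = c("P1", "P2")
#'   ),
#'   seed = 1
#' )
make_ppi <- function(proteins = character(), seed_protein, tier_design,
                     n_extra_edges = 0L, seed = 0L) {
  tiers <- list(
    related = tier_design$related %||% character(),
    tier3 = tier_design$tier3 %||% character(),
    tier2 = tier_design$tier2 %||% character(),
    peripheral = tier_design$peripheral %||% character()
  )
  all_tier <- unlist(tiers, use.names = FALSE)
  if (anyDuplicated(all_tier) || seed_protein %in% all_tier) {
    stop("tier design sets must be disjoint and exclude the seed",
      call. = FALSE
    )
  }
  core <- c(seed_protein, tiers$related)
  need <- c(tier3 = 3L, tier2 = 2L, peripheral = 1L)
  for (tn in names(need)) {
    if (length(tiers[[tn]]) && need[[tn]] > length(core)) {
      stop(sprintf(
        "tier '%s' needs %d partners but {seed} + related has only %d members",
        tn, need[[tn]], length(core)
      ), call. = FALSE)
    }
  }

  set.seed(derive_seed(seed, "ppi"))
  edges <- list()
  if (length(tiers$related)) {
    edges[[1L]] <- cbind(seed_protein, tiers$related)
  }
  for (tn in names(need)) {
    for (p in tiers[[tn]]) {
      partners <- if (need[[tn]] == length(core)) {
        core
      } else {
        sample(core, need[[tn]])
      }
      edges[[length(edges) + 1L]] <- cbind(p, partners)
    }
  }
  outside <- setdiff(unique(c(proteins, tiers$tier3, tiers$tier2, tiers$peripheral)), core)
  if (n_extra_edges > 0L) {
    if (length(outside) < 2L) {
      stop("need >= 2 non-core proteins for extra edges", call. = FALSE)
    }
    for (e in seq_len(n_extra_edges)) {
      pair <- sample(outside, 2L)
      edges[[length(edges) + 1L]] <- cbind(pair[1L], pair[2L])
    }
  }
  em <- do.call(rbind, edges)
  # canonical order + dedup: undirected simple graph
  a <- pmin(em[, 1L], em[, 2L])
  b <- pmax(em[, 1L], em[, 2L])
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  out_edges <- tibble::tibble(protein_a = a[keep], protein_b = b[keep])

  all_prot <- unique(c(core, outside))
  list(
    edges = out_edges,
    gene_protein_map = tibble::tibble(
      gene_id = paste0("g_", all_prot), protein_id = all_prot
    ),
    tier_design = tiers,
    seed_protein = seed_protein
  )
}
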