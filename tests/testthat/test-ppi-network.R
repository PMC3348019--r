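test_that("graph construction deduplicates, drops self-loops and reports bad rows", {
  expect_warning(
    g <- build_ppi_graph(tibble::tibble(
      a = c("A", "B", "A"), b = c("B", "A", "A")
    )),
    "self-loop"
  )
  expect_equal(igraph::ecount(g), 1L)
  expect_setequal(igraph::V(g)$name, c("A", "B"))

  empty <- build_ppi_graph(tibble::tibble(a = character(), b = character()))
  expect_equal(igraph::vcount(empty), 0L)

  expect_error(
    build_ppi_graph(tibble::tibble(a = c("A", NA), b = c("B", "C"))),
    "malformed edge row"
  )
})

test_that("graph degrees match a brute-force adjacency-set oracle", {
  edges <- random_edgelist(25L, 50L, seed = 31L)
  g <- suppressWarnings(build_ppi_graph(edges))
  oracle <- bruteforce_degrees(edges)
  deg <- igraph::degree(g)
  expect_equal(deg[names(oracle)], oracle)
})

test_that("rebuilding a graph from its own edge dump is the identity", {
  edges <- random_edgelist(15L, 40L, seed = 7L)
  g1 <- suppressWarnings(build_ppi_graph(edges))
  dump <- tibble::as_tibble(igraph::as_edgelist(g1), .name_repair = ~ c("a", "b"))
  g2 <- build_ppi_graph(dump)
  expect_equal(igraph::ecount(g2), igraph::ecount(g1))
  expect_setequal(igraph::V(g2)$name, igraph::V(g1)$name)
  expect_equal(
    igraph::degree(g2)[igraph::V(g1)$name],
    igraph::degree(g1)[igraph::V(g1)$name]
  )
})

test_that("interaction counts are unique partners with unmapped genes set aside", {
  g <- build_ppi_graph(tibble::tibble(
    a = c("P", "P", "P", "Q", "ISO2"),
    b = c("Q", "R", "S", "R", "ISO3")
  ))
  # isolated node: present but no partners
  g <- igraph::add_vertices(g, 1L, name = "ISO")
  map <- tibble::tibble(
    gene_id = c("gP", "gQ", "gISO"),
    protein_id = c("P", "Q", "ISO")
  )
  tab <- interaction_counts(g, c("gP", "gQ", "gISO", "gNONE"), map)
  expect_equal(tab$n_ppi[tab$gene_id == "gP"], 3L) # partners {Q,R,S}
  expect_equal(tab$n_ppi[tab$gene_id == "gQ"], 2L)
  expect_equal(tab$n_ppi[tab$gene_id == "gISO"], 0L)
  expect_false("gNONE" %in% tab$gene_id)
  expect_equal(attr(tab, "unmapped"), "gNONE")
})

test_that("the degree filter is strict and monotone", {
  tab <- tibble::tibble(
    gene_id = c("A", "B", "C"), protein_id = c("pA", "pB", "pC"),
    n_ppi = c(10L, 11L, 30L)
  )
  expect_equal(filter_by_degree(tab, 10L)$gene_id, c("B", "C")) # strict >
  expect_equal(filter_by_degree(tab[0L, ], 10L)$gene_id, character())
  prev <- nrow(tab)
  for (mc in c(0L, 5L, 10L, 11L, 100L)) {
    cur <- nrow(filter_by_degree(tab, mc))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("the bundled worked-example table reproduces the published counts", {
  tab <- alzheimer_ppi_table()
  expect_equal(nrow(tab), 33L)
  kept <- filter_by_degree(tab, 10L)
  expect_equal(nrow(kept), 33L) # every row exceeds the >10 filter
  expect_equal(max(tab$n_ppi), 161L)
  expect_equal(tab$gene_id[which.max(tab$n_ppi)], "MAPK1")
  expect_equal(min(tab$n_ppi), 12L)
})

test_that("the related set is the seed neighborhood, optionally restricted", {
  g <- build_ppi_graph(tibble::tibble(
    a = c("S", "S", "S", "X"), b = c("X", "Y", "Z", "Y")
  ))
  expect_setequal(seed_related_set(g, "S"), c("X", "Y", "Z"))
  expect_equal(seed_related_set(g, "S", restrict = "X"), "X")
  expect_error(seed_related_set(g, "missing"), "absent")
})

test_that("node tiers follow unique-neighbor counts into the core set", {
  # hand-built toy graph around seed S with related {R1, R2, R3}
  edges <- tibble::tibble(
    a = c("S", "S", "S", "T3", "T3", "T3", "T3", "T2", "T2", "P1", "OUT"),
    b = c("R1", "R2", "R3", "S", "R1", "R2", "R3", "R1", "R2", "R3", "FAR")
  )
  g <- build_ppi_graph(edges)
  tiers <- classify_nodes(g, "S", c("R1", "R2", "R3"))
  tt <- stats::setNames(as.character(tiers$tier), tiers$protein)
  expect_equal(tt[["T3"]], "tier3plus") # k = 4 >= 3
  expect_equal(tt[["T2"]], "tier2")
  expect_equal(tt[["P1"]], "peripheral")
  expect_false("OUT" %in% tiers$protein) # not adjacent to the core
  expect_false("FAR" %in% tiers$protein)
  expect_equal(sum(tiers$tier == "seed"), 1L)
  # exact-3 reading available: k = 4 becomes unclassified
  tiers3 <- classify_nodes(g, "S", c("R1", "R2", "R3"), rule = "exact3")
  tt3 <- stats::setNames(as.character(tiers3$tier), tiers3$protein)
  expect_equal(tt3[["T3"]], "unclassified")
})

test_that("tier partition matches brute-force counting on random graphs", {
  for (rep in 1:10) {
    edges <- random_edgelist(60L, 150L, seed = 500L + rep)
    g <- suppressWarnings(build_ppi_graph(edges))
    nodes <- igraph::V(g)$name
    seedp <- nodes[1L]
    related <- setdiff(nodes[2:6], seedp)
    tiers <- classify_nodes(g, seedp, related)
    oracle <- bruteforce_tiers(edges, seedp, related)
    got <- tiers[!(tiers$tier %in% c("seed", "related")), ]
    expect_setequal(got$protein, names(oracle))
    expect_equal(
      as.character(got$tier)[match(names(oracle), got$protein)],
      unname(unlist(oracle))
    )
    # partition: tiers disjoint and cover the subnetwork exactly once
    expect_false(anyDuplicated(tiers$protein) > 0L)
  }
})

test_that("subnetwork extraction induces the tiered nodes with annotated edges", {
  edges <- tibble::tibble(
    a = c("S", "S", "T2", "T2", "OUT"),
    b = c("R1", "R2", "R1", "R2", "FAR")
  )
  g <- build_ppi_graph(edges)
  tiers <- classify_nodes(g, "S", c("R1", "R2"))
  sub <- extract_subnetwork(g, tiers)
  expect_setequal(igraph::V(sub$subgraph)$name, c("S", "R1", "R2", "T2"))
  expect_equal(nrow(sub$edges), 4L)
  expect_true(all(c(sub$edges$tier_a, sub$edges$tier_b) %in%
    c("seed", "related", "tier2")))

  # degenerate: no related set and no core-adjacent nodes -> seed alone
  g2 <- igraph::graph_from_data_frame(
    data.frame(a = "A", b = "B"),
    directed = FALSE,
    vertices = data.frame(name = c("A", "B", "S"))
  )
  tiers2 <- classify_nodes(g2, "S", character())
  sub2 <- extract_subnetwork(g2, tiers2)
  expect_equal(igraph::vcount(sub2$subgraph), 1L)
  expect_equal(nrow(sub2$edges), 0L)
})
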