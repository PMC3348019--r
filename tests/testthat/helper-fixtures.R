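# Fixtures are built in code at test time; nothing is stored on disk.

# A single straight tube along +x inside a small grid, with spherical seed
# and target ROIs at the two ends. Geometry is simple enough that tube
# membership, expected streamline length and retention all have closed
# forms.
straight_tube_config <- function(radius = 2, fraction = 0.6, kappa = Inf) {
  rois <- tibble::tibble(
    name = c("segA", "segB"),
    hemisphere = "left",
    cx = c(5, 25), cy = 6, cz = 6,
    radius = 2
  )
  tracts <- tibble::tibble(
    tract_id = "left_segA_segB",
    seed = "segA", target = "segB", hemisphere = "left",
    ctrl = list(rbind(c(5, 6, 6), c(25, 6, 6))),
    radius = radius, fraction = fraction
  )
  phantom_config(
    grid_shape = c(30L, 12L, 12L), rois = rois, tracts = tracts,
    kappa = kappa, seed = 0L
  )
}

straight_tube_phantom <- function(...) {
  make_phantom(straight_tube_config(...))
}

# Two coplanar tubes crossing orthogonally: "major" along +x (larger
# fiber fraction), "minor" along +y. At a 90-degree crossing the
# transverse population is never curvature-compatible with a transiting
# streamline, so two-population sampling lets each tract pass along its
# own population, while dropping the minor population strands the minor
# tract at the crossing. Used by the paired crossing-sampling runs.
crossing_config <- function(f_major = 0.55, f_minor = 0.35, kappa = 400) {
  rois <- tibble::tibble(
    name = c("majA", "majB", "minA", "minB"),
    hemisphere = "left",
    cx = c(5, 31, 18, 18),
    cy = c(18, 18, 5, 31),
    cz = 6,
    radius = 1.8
  )
  tracts <- tibble::tibble(
    tract_id = c("left_majA_majB", "left_minA_minB"),
    seed = c("majA", "minA"), target = c("majB", "minB"),
    hemisphere = "left",
    ctrl = list(
      rbind(c(5, 18, 6), c(31, 18, 6)),
      rbind(c(18, 5, 6), c(18, 31, 6))
    ),
    radius = 2, fraction = c(f_major, f_minor)
  )
  phantom_config(
    grid_shape = c(36L, 36L, 12L), rois = rois, tracts = tracts,
    kappa = kappa, seed = 0L
  )
}

# Drop the second (minor) population wherever two populations coexist,
# emulating single-fiber modelling of a crossing region.
drop_minor_population <- function(field) {
  orientation_field(
    dir1 = field$dir1, f1 = field$f1,
    dir2 = array(0, c(field$dim, 3L)), f2 = array(0, field$dim),
    kappa1 = field$kappa1, kappa2 = Inf, affine = field$affine
  )
}

# Small deterministic expression fixture: g genes x s samples with named
# dims, values drawn under a fixed seed.
random_expression <- function(n_probes = 10L, n_samples = 5L, seed = 42L) {
  set.seed(seed)
  x <- matrix(rnorm(n_probes * n_samples, 7, 1), n_probes, n_samples)
  dimnames(x) <- list(
    sprintf("p%02d", seq_len(n_probes)),
    sprintf("s%02d", seq_len(n_samples))
  )
  x
}

# Brute-force degree oracle over a raw edge list (set semantics,
# independent of igraph): unique partners per node, loops ignored.
bruteforce_degrees <- function(edges) {
  edges <- as.data.frame(edges)
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  vapply(nodes, function(v) {
    partners <- unique(c(
      edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v]
    ))
    length(setdiff(partners, v))
  }, integer(1))
}

# Brute-force tier oracle: k(v) by scanning the edge list.
bruteforce_tiers <- function(edges, seed_protein, related) {
  edges <- as.data.frame(edges)
  core <- union(seed_protein, related)
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  out <- list()
  for (v in setdiff(nodes, core)) {
    partners <- setdiff(unique(c(
      edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v]
    )), v)
    k <- length(intersect(partners, core))
    if (k == 0L) next
    out[[v]] <- if (k >= 3L) "tier3plus" else if (k == 2L) "tier2" else "peripheral"
  }
  out
}

# Random simple graph edge list over n nodes.
random_edgelist <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  tibble::tibble(from = a[keep], to = b[keep])
}
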