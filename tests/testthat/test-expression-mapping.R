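test_that("probe z-scores match the definitional oracle", {
  # symmetric two-point case: population sd 1, z = (-1, +1)
  m <- rbind(p1 = c(6, 8))
  colnames(m) <- c("s1", "s2")
  pz <- probe_zscores(m)
  expect_equal(unname(pz$z[1L, ]), c(-1, 1))
  expect_equal(pz$stats$mu, 7)
  expect_equal(pz$stats$sigma, 1)

  # random matrix: recompute from the definition, row means 0, pop sd 1
  x <- random_expression(10L, 5L)
  pz <- probe_zscores(x)
  mu <- rowMeans(x)
  sg <- sqrt(rowMeans((x - mu)^2))
  expect_equal(pz$z, (x - mu) / sg)
  expect_true(all(abs(rowMeans(pz$z)) < 1e-10))
  expect_true(all(abs(sqrt(rowMeans(pz$z^2)) - 1) < 1e-10))

  # sample-sd convention is available and differs by sqrt((n-1)/n)
  pz_s <- probe_zscores(x, sd = "sample")
  expect_equal(pz_s$z, pz$z * sqrt(4 / 5))
})

test_that("constant probes yield missing z-scores with a warning, never an error", {
  x <- rbind(flat = rep(3, 4), ok = c(1, 2, 3, 4))
  colnames(x) <- paste0("s", 1:4)
  expect_warning(pz <- probe_zscores(x), "constant probe")
  expect_true(all(is.na(pz$z["flat", ])))
  expect_true(all(is.finite(pz$z["ok", ])))
  expect_error(probe_zscores(x[, 1L, drop = FALSE]), ">= 2 samples")
})

test_that("gene aggregation averages probe z-scores and skips missing values", {
  z <- rbind(
    pa = c(0.2, 0.5), pb = c(0.6, NA), pc = c(1.0, 2.0)
  )
  colnames(z) <- c("s1", "s2")
  map <- tibble::tibble(
    probe_id = c("pa", "pb", "pc"), gene_id = c("g1", "g1", "g2")
  )
  gz <- gene_zscores(z, map, c("g1", "g2"))
  expect_equal(gz["g1", "s1"], mean(c(0.2, 0.6))) # 0.4, mean oracle
  expect_equal(gz["g1", "s2"], 0.5) # skip-missing rule
  expect_equal(gz["g2", ], z["pc", ]) # single-probe identity
  expect_error(gene_zscores(z, map, c("g1", "gX")), "gX")
})

test_that("pathway averages follow the arithmetic-mean definition", {
  z <- matrix(c(0.5, -0.5, 1.5), 1L,
    dimnames = list("g1", c("s1", "s2", "s3"))
  )
  out <- pathway_average(z, c("s1", "s2", "s3"), "pw")
  expect_equal(out$avg_z, 0.5)
  expect_equal(out$n, 3L)

  single <- pathway_average(z, "s2", "pw")
  expect_equal(single$avg_z, -0.5) # n = 1: average equals the sample z
  expect_equal(single$n, 1L)

  expect_warning(none <- pathway_average(z, character(), "pw"), "no samples")
  expect_equal(nrow(none), 0L)

  z2 <- rbind(z, g2 = c(NA, NA, NA))
  expect_warning(out2 <- pathway_average(z2, c("s1", "s3"), "pw"), "omitted")
  expect_equal(out2$gene_id, "g1")
  expect_equal(out2$n, 2L)
})

test_that("sample selection respects the mask, bounds and idempotence", {
  mask <- array(FALSE, c(10L, 10L, 10L))
  mask[3:5, 3:5, 3:5] <- TRUE
  aff <- affine_transform(diag(4))
  smp <- tibble::tibble(
    sample_id = c("in1", "in2", "out", "oob"),
    x = c(3.5, 4.2, 8.0, 30.0),
    y = c(3.5, 4.8, 8.0, 1.0),
    z = c(3.5, 3.1, 8.0, 1.0)
  )
  expect_warning(sel <- samples_in_pathway(smp, mask, aff), "outside")
  expect_setequal(sel$sample_id, c("in1", "in2"))
  expect_equal(attr(sel, "n_out_of_bounds"), 1L)
  # idempotent and order-independent
  sel2 <- suppressWarnings(samples_in_pathway(sel, mask, aff))
  expect_equal(sel2$sample_id, sel$sample_id)
  shuffled <- smp[c(3, 1, 4, 2), ]
  sel3 <- suppressWarnings(samples_in_pathway(shuffled, mask, aff))
  expect_setequal(sel3$sample_id, sel$sample_id)

  empty_mask <- array(FALSE, c(10L, 10L, 10L))
  expect_equal(
    nrow(suppressWarnings(samples_in_pathway(smp, empty_mask, aff))), 0L
  )
})

test_that("forced in-tube samples are exactly the ones a tube mask selects", {
  ph <- straight_tube_phantom(radius = 2)
  smp <- make_samples(ph, 10L, in_tube = c(left_segA_segB = 10L), seed = 8L)
  # geometric tube mask built independently from the centerline
  dims <- ph$config$grid_shape
  grid <- as.matrix(expand.grid(
    i = 0:(dims[1] - 1), j = 0:(dims[2] - 1), k = 0:(dims[3] - 1)
  ))
  # dilate by the half voxel diagonal so every voxel that can contain an
  # in-tube point is covered
  d <- fiberlink:::distance_to_tract(ph, grid + 0.5, "left_segA_segB")
  mask <- array(FALSE, dims)
  mask[grid[d <= 2 + sqrt(3) / 2, , drop = FALSE] + 1L] <- TRUE
  sel <- samples_in_pathway(smp, mask, ph$affine)
  expect_setequal(sel$sample_id, smp$sample_id)
})

test_that("the z-score chain matches a brute-force re-derivation from raw intensities", {
  set.seed(99)
  x <- random_expression(12L, 8L, seed = 99L)
  map <- tibble::tibble(
    probe_id = rownames(x),
    gene_id = rep(sprintf("g%d", 1:4), each = 3L)
  )
  genes <- sprintf("g%d", 1:4)
  sel <- c("s02", "s05", "s07")

  out <- pathway_average(
    gene_zscores(probe_zscores(x), map, genes), sel, "pw"
  )

  # independent chain: definitions applied longhand per gene and sample
  for (g in genes) {
    probes <- map$probe_id[map$gene_id == g]
    zs <- sapply(sel, function(s) {
      mean(sapply(probes, function(p) {
        (x[p, s] - mean(x[p, ])) / sqrt(mean((x[p, ] - mean(x[p, ]))^2))
      }))
    })
    expect_equal(out$avg_z[out$gene_id == g], mean(zs), tolerance = 1e-12)
    expect_equal(out$n[out$gene_id == g], length(sel))
  }
})

test_that("planted genes rank at the top of the pathway average z-scores", {
  ph <- straight_tube_phantom()
  reg <- ph$labels$registry
  sv <- roi_voxels(ph$labels, reg$label[reg$name == "segA"])
  tm <- ph$labels$lattice == reg$label[reg$name == "segB"]
  pr <- track_pathway(ph$field, sv, tm, tracking_params(n_per_seed = 15L),
    seed = 1L
  )
  ann <- make_gene_annotation(40L, 2L)
  planted_genes <- c("G004", "G017", "G023")
  planted <- tibble::tibble(
    gene_id = planted_genes, tract_id = "left_segA_segB", delta = 3
  )
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    smp <- make_samples(ph, 150L,
      in_tube = c(left_segA_segB = 15L), seed = 1000L + r
    )
    x <- make_expression(smp, ann$probe_gene_map, planted,
      noise_sd = 0.5, seed = 2000L + r
    )
    sel <- samples_in_pathway(smp, pr$mask, ph$affine)
    gz <- gene_zscores(probe_zscores(x), ann$probe_gene_map, ann$genes)
    avg <- pathway_average(gz, sel$sample_id, "tube")
    top <- avg$gene_id[order(-avg$avg_z)][seq_along(planted_genes)]
    if (setequal(top, planted_genes)) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})
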