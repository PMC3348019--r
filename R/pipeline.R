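#' Pipeline configuration
#'
#' Assembles everything one end-to-end run needs: either `synthetic = TRUE`
#' (inputs generated by the phantom/sample/expression/PPI simulators) or a
#' list of input file paths, plus tracking, normalization and network
#' options and a single master seed from which every stage derives its own
#' substream. Values are stored as given; [validate_config()] reports
#' problems as data and [run_pipeline()] refuses to start on any error
#' finding.
#'
#' @param synthetic Generate all inputs in memory (default) or read them
#'   from `inputs`.
#' @param inputs When `synthetic = FALSE`: a named list of paths —
#'   `labels_nifti`, `registry_tsv`, `field_nifti`, `samples_tsv`,
#'   `expression_tsv`, `probe_gene_tsv`, `disease_genes_tsv`,
#'   `gene_protein_tsv`, `ppi_tsv`.
#' @param phantom A [phantom_config()] (synthetic mode).
#' @param n_samples,in_tube,noise_sd,planted Sample/expression simulation
#'   settings (see [make_samples()], [make_expression()]).
#' @param seed_structure Name of the bilateral seed structure.
#' @param targets Target structure names; `NULL` means every non-seed
#'   structure in the registry (midline ones are excluded at enumeration).
#' @param tracking Named list overriding [tracking_params()] defaults.
#' @param normalization List: `sd` ("population"/"sample"), `scope`
#'   ("global"/"pathway").
#' @param network List: `min_count` (strict degree filter threshold),
#'   `tier_rule` ("at_least3"/"exact3").
#' @param seed_protein,related_roster Seed protein id and optional curated
#'   restriction roster for the related set (synthetic mode fills these
#'   from the PPI design when left `NULL`).
#' @param ppi_design Tier design list for [make_ppi()] (synthetic mode).
#' @param n_genes,probes_per_gene,n_disease_genes Synthetic annotation
#'   sizes.
#' @param seed Master seed.
#' @return An object of class `fiberlink_config`.
#' @export
fiberlink_config <- function(synthetic = TRUE,
                             inputs = NULL,
                             phantom = default_phantom_config(),
                             n_samples = 200L,
                             in_tube = 0.5,
                             noise_sd = 0.5,
                             planted = NULL,
                             seed_structure = "hippocampus",
                             targets = NULL,
                             tracking = list(),
                             normalization = list(),
                             network = list(),
                             seed_protein = NULL,
                             related_roster = NULL,
                             ppi_design = NULL,
                             n_genes = 60L,
                             probes_per_gene = 2L,
                             n_disease_genes = 40L,
                             seed = 0L) {
  trk <- utils::modifyList(
    list(
      step_size = 0.5, curvature_thresh = 80, n_per_seed = 100L,
      max_steps = 2000L, min_fraction = 0.05, mask_threshold = 1L
    ),
    tracking
  )
  nrm <- utils::modifyList(
    list(sd = "population", scope = "global"), normalization
  )
  net <- utils::modifyList(
    list(min_count = 10L, tier_rule = "at_least3"), network
  )
  if (synthetic && is.null(planted)) {
    planted <- tibble::tibble(
      gene_id = c("G001", "G002", "G003"),
      tract_id = c(
        "left_hippocampus_thalamus", "right_hippocampus_thalamus",
        "left_hippocampus_amygdala"
      ),
      delta = 3
    )
  }
  if (synthetic && is.null(ppi_design)) {
    pid <- function(i) sprintf("P%03d", i)
    ppi_design <- list(
      related = pid(1:6), tier3 = pid(7:10), tier2 = pid(11:16),
      peripheral = pid(17:30)
    )
    if (is.null(seed_protein)) seed_protein <- "APPX"
  }
  structure(
    list(
      synthetic = synthetic, inputs = inputs, phantom = phantom,
      n_samples = as.integer(n_samples), in_tube = in_tube,
      noise_sd = noise_sd, planted = planted,
      seed_structure = seed_structure, targets = targets,
      tracking = trk, normalization = nrm, network = net,
      seed_protein = seed_protein, related_roster = related_roster,
      ppi_design = ppi_design, n_genes = as.integer(n_genes),
      probes_per_gene = as.integer(probes_per_gene),
      n_disease_genes = as.integer(n_disease_genes),
      seed = as.integer(seed)
    ),
    class = "fiberlink_config"
  )
}

#' Validate a pipeline configuration
#'
#' Returns findings as data: a tibble with `level` (`"error"` or
#' `"warning"`) and `message`. An empty tibble means the configuration is
#' runnable. Errors cover invalid numeric parameters and missing input
#' files; warnings flag suspicious values such as a curvature threshold of
#' 90 degrees or more.
#'
#' @param config A [fiberlink_config()].
#' @return A tibble of findings (possibly zero rows).
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      level = level, message = msg
    )
  }
  trk <- config$tracking
  if (trk$step_size <= 0) add("error", "tracking step_size must be > 0")
  if (trk$n_per_seed <= 0) add("error", "tracking n_per_seed must be > 0")
  if (trk$max_steps <= 0) add("error", "tracking max_steps must be > 0")
  if (trk$min_fraction <= 0 || trk$min_fraction > 1) {
    add("error", "tracking min_fraction must be in (0, 1]")
  }
  if (trk$mask_threshold <= 0) add("error", "mask_threshold must be > 0")
  if (trk$curvature_thresh <= 0 || trk$curvature_thresh > 180) {
    add("error", "curvature_thresh must be in (0, 180]")
  } else if (trk$curvature_thresh >= 90) {
    add("warning", "curvature_thresh >= 90 degrees permits sharp reversals")
  }
  if (!config$normalization$sd %in% c("population", "sample")) {
    add("error", "normalization sd must be 'population' or 'sample'")
  }
  if (!config$normalization$scope %in% c("global", "pathway")) {
    add("error", "normalization scope must be 'global' or 'pathway'")
  }
  if (config$network$min_count < 0) add("error", "network min_count must be >= 0")
  if (!config$network$tier_rule %in% c("at_least3", "exact3")) {
    add("error", "network tier_rule must be 'at_least3' or 'exact3'")
  }
  if (config$synthetic) {
    if (config$n_samples < 1) add("error", "n_samples must be >= 1")
    if (config$noise_sd < 0) add("error", "noise_sd must be >= 0")
  } else {
    needed <- c(
      "labels_nifti", "registry_tsv", "field_nifti", "samples_tsv",
      "expression_tsv", "probe_gene_tsv", "disease_genes_tsv",
      "gene_protein_tsv", "ppi_tsv"
    )
    for (nm in needed) {
      path <- config$inputs[[nm]]
      if (is.null(path)) {
        add("error", sprintf("input path '%s' missing", nm))
      } else if (!file.exists(path)) {
        add("error", sprintf("input file not found: %s", path))
      }
    }
    if (is.null(config$seed_protein)) {
      add("error", "seed_protein must be set when inputs are files")
    }
  }
  if (length(findings)) {
    dplyr::bind_rows(findings)
  } else {
    tibble::tibble(level = character(), message = character())
  }
}

# Generate or load every pipeline input; returns a named list.
assemble_inputs <- function(config) {
  if (config$synthetic) {
    cfg_ph <- config$phantom
    cfg_ph$seed <- derive_seed(config$seed, "phantom")
    phantom <- make_phantom(cfg_ph)
    samples <- make_samples(
      phantom, config$n_samples, config$in_tube,
      seed = derive_seed(config$seed, "samples")
    )
    ann <- make_gene_annotation(config$n_genes, config$probes_per_gene)
    expression <- make_expression(
      samples, ann$probe_gene_map, config$planted,
      noise_sd = config$noise_sd,
      seed = derive_seed(config$seed, "expression")
    )
    disease_genes <- ann$genes[seq_len(config$n_disease_genes)]
    gene_protein <- tibble::tibble(
      gene_id = ann$genes,
      protein_id = sprintf("P%03d", seq_along(ann$genes))
    )
    ppi <- make_ppi(
      proteins = c(gene_protein$protein_id, sprintf("X%02d", 1:10)),
      seed_protein = config$seed_protein,
      tier_design = config$ppi_design,
      n_extra_edges = 20L,
      seed = derive_seed(config$seed, "ppi")
    )
    related_roster <- config$related_roster %||% config$ppi_design$related
    list(
      labels = phantom$labels, field = phantom$field,
      affine = phantom$affine, phantom = phantom,
      samples = samples, expression = expression,
      probe_gene_map = ann$probe_gene_map,
      disease_genes = disease_genes, gene_protein_map = gene_protein,
      ppi_edges = ppi$edges, seed_protein = config$seed_protein,
      related_roster = related_roster
    )
  } else {
    paths <- config$inputs
    labels <- read_label_volume(paths$labels_nifti, paths$registry_tsv)
    field <- read_orientation_field(paths$field_nifti)
    samples <- readr::read_tsv(paths$samples_tsv, show_col_types = FALSE)
    expr_df <- readr::read_tsv(paths$expression_tsv, show_col_types = FALSE)
    expression <- as.matrix(expr_df[, -1L])
    rownames(expression) <- expr_df[[1L]]
    list(
      labels = labels, field = field, affine = labels$affine,
      phantom = NULL, samples = samples, expression = expression,
      probe_gene_map = readr::read_tsv(paths$probe_gene_tsv,
        show_col_types = FALSE
      ),
      disease_genes = readr::read_tsv(paths$disease_genes_tsv,
        show_col_types = FALSE
      )$gene_id,
      gene_protein_map = readr::read_tsv(paths$gene_protein_tsv,
        show_col_types = FALSE
      ),
      ppi_edges = readr::read_tsv(paths$ppi_tsv, show_col_types = FALSE),
      seed_protein = config$seed_protein,
      related_roster = config$related_roster
    )
  }
}

#' Run the full pipeline
#'
#' Executes simulate/load -> tractography -> expression mapping -> network
#' analysis and returns a report bundle. Identical config and seed give a
#' byte-identical bundle; tasks with zero retained streamlines still
#' appear in the pathway table with zeros. Warnings raised by any stage
#' (constant probes, out-of-bounds samples, self-loops, empty pathways)
#' are collected into the manifest instead of being lost.
#'
#' @param config A [fiberlink_config()].
#' @param out_dir Optional directory; when given, all bundle tables, the
#'   manifest and the per-task NIfTI volumes are written there (see
#'   [write_report_bundle()]).
#' @return An object of class `report_bundle`: `pathway_table` (one row
#'   per enumerated task: hemisphere, seed, target, n_voxels, n_retained,
#'   n_samples), `gene_summary` (long per-pathway per-gene average
#'   z-scores), `interaction_table`, `filtered_genes`, `tiers`,
#'   `subnetwork_edges`, `pathways` (list of [track_pathway()] results)
#'   and `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- fiberlink_config(n_samples = 50, tracking = list(n_per_seed = 10))
#' bundle <- run_pipeline(cfg)
#' bundle$pathway_table
#' }
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "fiberlink_config"))
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop(
      "invalid configuration:\n",
      paste("-", findings$message[findings$level == "error"],
        collapse = "\n"
      ),
      call. = FALSE
    )
  }
  warnings_log <- character()
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          call. = FALSE
        )
      }),
      warning = function(w) {
        warnings_log <<- c(
          warnings_log, sprintf("[%s] %s", name, conditionMessage(w))
        )
        invokeRestart("muffleWarning")
      }
    )
  }

  inputs <- stage("inputs", assemble_inputs(config))
  registry <- inputs$labels$registry
  targets <- config$targets %||%
    setdiff(unique(registry$name), config$seed_structure)
  tasks <- stage(
    "enumerate",
    suppressMessages(
      enumerate_pathway_tasks(registry, config$seed_structure, targets)
    )
  )

  params <- tracking_params(
    step_size = config$tracking$step_size,
    curvature_thresh = config$tracking$curvature_thresh,
    n_per_seed = config$tracking$n_per_seed,
    max_steps = config$tracking$max_steps,
    min_fraction = config$tracking$min_fraction,
    mask_threshold = config$tracking$mask_threshold,
    seed = derive_seed(config$seed, "tracking")
  )
  pathways <- stage("tractography", {
    purrr::map(seq_len(nrow(tasks)), function(i) {
      task <- tasks[i, ]
      track_pathway(
        inputs$field,
        roi_voxels(inputs$labels, task$seed_label),
        inputs$labels$lattice == task$target_label,
        params,
        seed = params$seed,
        seed_name = paste(task$hemisphere, task$seed_name),
        target_name = paste(task$hemisphere, task$target_name)
      )
    })
  })
  names(pathways) <- tasks$task_id

  mapping <- stage("expression-mapping", {
    pz <- probe_zscores(inputs$expression, sd = config$normalization$sd)
    gz <- gene_zscores(pz, inputs$probe_gene_map, inputs$disease_genes)
    per_task <- purrr::map(seq_len(nrow(tasks)), function(i) {
      pr <- pathways[[i]]
      sel <- samples_in_pathway(inputs$samples, pr$mask, inputs$affine)
      if (config$normalization$scope == "pathway" &&
        nrow(sel) >= 2L) {
        pz_loc <- probe_zscores(
          inputs$expression[, sel$sample_id, drop = FALSE],
          sd = config$normalization$sd
        )
        gz_loc <- gene_zscores(
          pz_loc, inputs$probe_gene_map, inputs$disease_genes
        )
        summary <- pathway_average(gz_loc, sel$sample_id, tasks$task_id[i])
      } else {
        summary <- pathway_average(gz, sel$sample_id, tasks$task_id[i])
      }
      list(n_samples = nrow(sel), summary = summary)
    })
    list(
      stats = pz$stats,
      n_samples = vapply(per_task, `[[`, integer(1), "n_samples"),
      gene_summary = dplyr::bind_rows(
        purrr::map(per_task, "summary")
      )
    )
  })

  network <- stage("network", {
    graph <- build_ppi_graph(inputs$ppi_edges)
    counts <- interaction_counts(
      graph, inputs$disease_genes, inputs$gene_protein_map
    )
    filtered <- filter_by_degree(counts, config$network$min_count)
    related <- seed_related_set(
      graph, inputs$seed_protein,
      restrict = inputs$related_roster
    )
    tiers <- classify_nodes(
      graph, inputs$seed_protein, related,
      rule = config$network$tier_rule
    )
    subnet <- extract_subnetwork(graph, tiers)
    list(
      graph = graph, counts = counts, filtered = filtered,
      tiers = tiers, subnetwork = subnet
    )
  })

  pathway_table <- dplyr::mutate(
    tasks,
    n_voxels = unname(vapply(pathways, `[[`, integer(1), "n_voxels")),
    n_retained = unname(vapply(pathways, `[[`, integer(1), "n_retained")),
    n_samples = mapping$n_samples
  )

  manifest <- list(
    package = "fiberlink",
    version = as.character(utils::packageVersion("fiberlink")),
    master_seed = config$seed,
    synthetic = config$synthetic,
    tracking = config$tracking,
    normalization = config$normalization,
    network = config$network,
    n_samples = config$n_samples,
    noise_sd = config$noise_sd,
    seed_protein = inputs$seed_protein,
    warnings = warnings_log
  )

  bundle <- structure(
    list(
      pathway_table = pathway_table,
      gene_summary = mapping$gene_summary,
      probe_stats = mapping$stats,
      interaction_table = network$counts,
      filtered_genes = network$filtered,
      tiers = network$tiers,
      subnetwork_edges = network$subnetwork$edges,
      pathways = pathways,
      manifest = manifest
    ),
    class = "report_bundle"
  )
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(
    "<report_bundle> ", nrow(x$pathway_table), " pathway tasks (",
    sum(x$pathway_table$n_voxels > 0), " nonempty), ",
    nrow(x$interaction_table), " disease genes, ",
    nrow(x$filtered_genes), " above the degree filter, ",
    nrow(x$tiers), " tiered proteins\n",
    sep = ""
  )
  invisible(x)
}

#' Write a report bundle to disk
#'
#' All tables as TSV with header rows, the manifest as YAML, and one
#' visitation-count plus one mask NIfTI per task.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param volumes Write per-task NIfTI volumes too.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, volumes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$pathway_table, file.path(dir, "pathway_table.tsv"))
  gs <- dplyr::select(bundle$gene_summary, -"sample_ids")
  readr::write_tsv(gs, file.path(dir, "gene_summary.tsv"))
  readr::write_tsv(
    bundle$interaction_table, file.path(dir, "interaction_table.tsv")
  )
  readr::write_tsv(bundle$filtered_genes, file.path(dir, "filtered_genes.tsv"))
  readr::write_tsv(
    tibble::as_tibble(bundle$tiers), file.path(dir, "tiers.tsv")
  )
  readr::write_tsv(
    bundle$subnetwork_edges, file.path(dir, "subnetwork_edges.tsv")
  )
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  if (volumes) {
    for (tid in names(bundle$pathways)) {
      pr <- bundle$pathways[[tid]]
      img <- RNifti::asNifti(pr$visit_count * 1)
      img <- RNifti::`sform<-`(
        img, structure(unclass(pr$affine), code = 2L)
      )
      RNifti::writeNifti(img, file.path(dir, paste0(tid, "_counts.nii.gz")))
      msk <- RNifti::asNifti(pr$mask * 1L)
      msk <- RNifti::`sform<-`(
        msk, structure(unclass(pr$affine), code = 2L)
      )
      RNifti::writeNifti(msk, file.path(dir, paste0(tid, "_mask.nii.gz")))
    }
  }
  invisible(dir)
}

#' Write a synthetic input bundle to disk
#'
#' Materialises every synthetic pipeline input in its on-disk exchange
#' format: label volume and orientation field as NIfTI, samples,
#' expression, probe-gene map, disease gene list, gene-protein map and
#' PPI edges as TSV, plus a YAML manifest recording the seeds and sizes.
#' A pipeline run over these files reproduces the in-memory synthetic run.
#'
#' @param config A synthetic [fiberlink_config()].
#' @param dir Output directory.
#' @return A named list of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(config, dir) {
  stopifnot(config$synthetic)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- assemble_inputs(config)
  paths <- list(
    labels_nifti = file.path(dir, "labels.nii.gz"),
    registry_tsv = file.path(dir, "registry.tsv"),
    field_nifti = file.path(dir, "orientation_field.nii.gz"),
    samples_tsv = file.path(dir, "samples.tsv"),
    expression_tsv = file.path(dir, "expression.tsv"),
    probe_gene_tsv = file.path(dir, "probe_gene.tsv"),
    disease_genes_tsv = file.path(dir, "disease_genes.tsv"),
    gene_protein_tsv = file.path(dir, "gene_protein.tsv"),
    ppi_tsv = file.path(dir, "ppi_edges.tsv")
  )
  write_label_volume(inputs$labels, paths$labels_nifti, paths$registry_tsv)
  write_orientation_field(inputs$field, paths$field_nifti)
  readr::write_tsv(inputs$samples, paths$samples_tsv)
  expr <- tibble::as_tibble(inputs$expression, rownames = "probe_id")
  readr::write_tsv(expr, paths$expression_tsv)
  readr::write_tsv(inputs$probe_gene_map, paths$probe_gene_tsv)
  readr::write_tsv(
    tibble::tibble(gene_id = inputs$disease_genes), paths$disease_genes_tsv
  )
  readr::write_tsv(inputs$gene_protein_map, paths$gene_protein_tsv)
  readr::write_tsv(inputs$ppi_edges, paths$ppi_tsv)
  yaml::write_yaml(
    list(
      master_seed = config$seed, n_samples = config$n_samples,
      noise_sd = config$noise_sd, seed_protein = inputs$seed_protein,
      related_roster = inputs$related_roster,
      grid_shape = config$phantom$grid_shape
    ),
    file.path(dir, "manifest.yaml")
  )
  invisible(paths)
}
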