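pipeline_defaults <- function() {
  list(
    k = 31L, mode = "em", detection_min = 1.0,
    min_genes = 1000, top_n_strains = 20, top_k_ogs = 200,
    alpha = 0.05, min_ref_genes = 10, n_perm = 999, seed = 1L,
    stages = list(quantify = TRUE, de = TRUE, rank = TRUE, enrich = TRUE,
                  regress = TRUE, ordinate = TRUE, compare = TRUE),
    sim = list()
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  cfg$stages <- utils::modifyList(pipeline_defaults()$stages,
                                  cfg$stages %||% list())
  cfg
}

write_stage <- function(outdir, name, tbl) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  flat <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
  num <- vapply(flat, is.numeric, logical(1))
  for (cn in names(flat)[num]) flat[[cn]] <- signif(flat[[cn]], 12)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

skip_stage <- function(results, name, reason) {
  results$skipped[[name]] <- reason
  results
}

#' Run the full SynCom metatranscriptomics pipeline on a simulated community
#'
#' Orchestrates every stage end to end from one configuration: catalog and
#' count simulation, read emission, k-mer assignment, duplicate resolution,
#' strain profiling and focal-strain selection, the four differential
#' expression analyses (per-strain genes, per-strain orthogroups,
#' community-scale orthogroups), cumulative-log2FC ranking, functional
#' enrichment, function-abundance regression, Bray-Curtis/PCoA/PERMANOVA
#' ordination and the RNA-vs-DNA profiling comparison. Every output table is
#' written as TSV under `outdir` together with a `manifest.json` recording
#' the configuration, seed and MD5 hash of each file, so a rerun with the
#' same config is byte-identical.
#'
#' @param config A list or YAML file path. Recognized top-level entries:
#'   `k`, `mode` (`"em"`/`"unique_only"`), `detection_min`, `min_genes`,
#'   `top_n_strains`, `top_k_ogs`, `alpha`, `min_ref_genes`, `n_perm`,
#'   `seed`, `stages` (named logical toggles: quantify, de, rank, enrich,
#'   regress, ordinate, compare) and `sim` (arguments for [sim_config()]).
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory stage results, the
#'   `skipped` record, and `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list(skipped = list())
  files <- character(0)
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[%s] stage %-12s (%.1fs elapsed)", "syncomtx", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  run_stage <- function(name, fn) {
    log_stage(name)
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulation ---------------------------------------------------------
  scfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed, k = cfg$k),
                                                cfg$sim))
  run_stage("simulate", function() {
    results$sim_catalog <<- simulate_catalog(scfg)
    results$sim_expr <<- simulate_expression(results$sim_catalog$catalog, scfg)
    results$reads <<- simulate_reads(results$sim_catalog$catalog,
                                     results$sim_expr$counts, scfg)
    results$amplicon <<- simulate_amplicon(results$sim_expr$truth, scfg)
  })
  catalog <- results$sim_catalog$catalog
  samples <- results$sim_expr$samples
  files <- c(files, write_stage(outdir, "samples", samples),
             write_stage(outdir, "catalog_annotation",
                         catalog[, c("gene_id", "strain_id", "kingdom",
                                     "orthogroup_id", "cog_category", "go_terms")]))

  # --- assignment and quantification --------------------------------------
  if (!isTRUE(cfg$stages$quantify)) {
    results <- skip_stage(results, "quantify", "stage toggled off")
    for (dep in c("de", "rank", "enrich", "regress", "ordinate", "compare")) {
      results <- skip_stage(results, dep, "skipped: dependency `quantify` off")
    }
  } else {
    run_stage("assign", function() {
      idx <- build_kmer_index(catalog, k = cfg$k)
      results$assignment <<- assign_reads(idx, results$reads, mode = cfg$mode)
      results$classes <<- idx$classes
    })
    run_stage("quantify", function() {
      mats <- resolve_duplicates(results$assignment$counts, results$classes)
      results$per_strain <<- mats$per_strain
      results$community <<- mats$community
      results$profile <<- strain_relative_abundance(mats$community,
                                                    classes = results$classes)
      results$detection <<- detect_strains(mats$community, samples,
                                           cfg$detection_min)
      results$focal <<- select_focal_strains(mats$per_strain, samples,
                                             results$profile,
                                             min_genes = cfg$min_genes,
                                             top_n = cfg$top_n_strains,
                                             detection_min = cfg$detection_min)
    })
    files <- c(files,
               write_stage(outdir, "class_counts", results$assignment$counts),
               write_stage(outdir, "per_strain_counts", results$per_strain),
               write_stage(outdir, "community_counts", results$community),
               write_stage(outdir, "strain_profile_rna", results$profile),
               write_stage(outdir, "strain_detection", results$detection),
               write_stage(outdir, "focal_strains",
                           tibble::tibble(strain_id = results$focal)))
  }

  # --- differential expression --------------------------------------------
  de_on <- isTRUE(cfg$stages$de) && !is.null(results$per_strain)
  if (isTRUE(cfg$stages$de) && is.null(results$per_strain)) {
    results <- skip_stage(results, "de", "skipped: dependency `quantify` off")
  }
  if (de_on) {
    run_stage("de", function() {
      focal <- results$focal
      results$gene_de <<- run_per_strain_de(
        results$per_strain, samples, focal_strains = focal,
        min_ref_genes = cfg$min_ref_genes, alpha_sig = cfg$alpha)
      microbial <- results$per_strain[results$per_strain$kingdom != "host", ]
      og_counts <- aggregate_by_og(microbial, samples)
      results$og_counts <<- og_counts
      results$og_de <<- run_per_strain_de(
        og_counts, samples, focal_strains = focal,
        min_ref_genes = cfg$min_ref_genes, alpha_sig = cfg$alpha)
      results$community_de <<- community_og_de(
        results$community, samples, min_ref_genes = cfg$min_ref_genes,
        alpha_sig = cfg$alpha)
    })
    files <- c(files,
               write_stage(outdir, "de_genes_per_strain", tidy(results$gene_de)),
               write_stage(outdir, "de_ogs_per_strain", tidy(results$og_de)),
               write_stage(outdir, "de_ogs_community", results$community_de$result))
  } else if (!isTRUE(cfg$stages$de)) {
    results <- skip_stage(results, "de", "stage toggled off")
  }

  # --- ranking, enrichment, regression ------------------------------------
  if (isTRUE(cfg$stages$rank) && !is.null(results$og_de)) {
    run_stage("rank", function() {
      results$ranking <<- cumulative_lfc_ranking(results$og_de,
                                                 results$community_de,
                                                 top_k = cfg$top_k_ogs)
    })
    files <- c(files, write_stage(outdir, "og_ranking_top", results$ranking),
               write_stage(outdir, "og_ranking_full", attr(results$ranking, "full")))
  } else if (isTRUE(cfg$stages$rank)) {
    results <- skip_stage(results, "rank", "skipped: dependency `de` off")
  } else {
    results <- skip_stage(results, "rank", "stage toggled off")
  }

  og_annotation <- annotate_ogs(catalog[catalog$kingdom != "host", ])
  if (isTRUE(cfg$stages$enrich) && !is.null(results$ranking)) {
    run_stage("enrich", function() {
      universe <- attr(results$ranking, "full")$orthogroup_id
      target <- results$ranking$orthogroup_id
      results$enrichment <<- fisher_go_enrichment(
        target, universe, annotation_pairs(og_annotation),
        alpha_sig = cfg$alpha)
    })
    files <- c(files, write_stage(outdir, "go_enrichment", results$enrichment))
  } else if (isTRUE(cfg$stages$enrich)) {
    results <- skip_stage(results, "enrich", "skipped: dependency `rank` off")
  } else {
    results <- skip_stage(results, "enrich", "stage toggled off")
  }

  if (isTRUE(cfg$stages$regress) && !is.null(results$ranking)) {
    run_stage("regress", function() {
      cat_lfc <- category_mean_lfc(results$ranking, results$og_de, og_annotation)
      results$cat_lfc <<- cat_lfc
      results$regression <<- tryCatch(
        function_abundance_regression(cat_lfc, results$profile, samples),
        error = function(e) NULL)
    })
    files <- c(files, write_stage(outdir, "category_mean_lfc", results$cat_lfc))
    if (!is.null(results$regression)) {
      files <- c(files,
                 write_stage(outdir, "function_abundance_fit",
                             results$regression$fit),
                 write_stage(outdir, "category_correlogram",
                             results$regression$correlogram))
    }
  } else if (isTRUE(cfg$stages$regress)) {
    results <- skip_stage(results, "regress", "skipped: dependency `rank` off")
  } else {
    results <- skip_stage(results, "regress", "stage toggled off")
  }

  # --- ordination ---------------------------------------------------------
  if (isTRUE(cfg$stages$ordinate) && !is.null(results$og_counts)) {
    run_stage("ordinate", function() {
      rel <- og_relative_counts(results$og_counts, samples)
      d <- bray_curtis(rel$table)
      results$pcoa <<- pcoa_ordination(d, n_axes = 2)
      results$permanova <<- permanova(
        d, rel$units, terms = c("compartment", "strain_id"),
        n_perm = cfg$n_perm, seed = cfg$seed)
      results$units <<- rel$units
    })
    files <- c(files,
               write_stage(outdir, "pcoa_coordinates", results$pcoa$coordinates),
               write_stage(outdir, "permanova", results$permanova))
  } else if (isTRUE(cfg$stages$ordinate)) {
    results <- skip_stage(results, "ordinate", "skipped: dependency `de` off")
  } else {
    results <- skip_stage(results, "ordinate", "stage toggled off")
  }

  # --- RNA vs DNA comparison ----------------------------------------------
  if (isTRUE(cfg$stages$compare) && !is.null(results$profile)) {
    run_stage("compare", function() {
      dna_flags <- results$amplicon |>
        dplyr::group_by(.data$strain_id, .data$compartment) |>
        dplyr::summarise(detected = any(.data$reads >= 1), .groups = "drop")
      results$detection_compare <<- compare_detection(results$detection, dna_flags)
      shared <- Reduce(intersect, results$detection_compare$both_ids)
      results$abundance_cor <<- tryCatch(
        correlate_abundances(results$profile, results$amplicon, shared),
        error = function(e) NULL)
    })
    files <- c(files,
               write_stage(outdir, "rna_dna_detection",
                           results$detection_compare))
    if (!is.null(results$abundance_cor)) {
      files <- c(files, write_stage(outdir, "rna_dna_correlation",
                                    results$abundance_cor))
    }
  } else if (isTRUE(cfg$stages$compare)) {
    results <- skip_stage(results, "compare", "skipped: dependency `quantify` off")
  } else {
    results <- skip_stage(results, "compare", "stage toggled off")
  }

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    skipped = results$skipped,
    package_version = as.character(utils::packageVersion("syncomtx")),
    files = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
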