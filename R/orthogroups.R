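#' Aggregate gene counts to orthogroup counts within each strain
#'
#' Sums member-gene counts to one count per orthogroup per strain per sample,
#' the unit of cross-strain comparative analyses. Genes missing from the map
#' fall back to singleton orthogroups named after the gene.
#'
#' @param per_strain Wide per-strain count tibble (needs `gene_id`,
#'   `strain_id`, sample columns).
#' @param og_map Tibble `gene_id` -> `orthogroup_id` (defaults to the
#'   `orthogroup_id` column already present in `per_strain`). Passing a
#'   different grouping (e.g. curated KEGG orthology labels) reruns the same
#'   aggregation under that scheme.
#' @param samples Sample metadata tibble.
#' @return Wide tibble: `feature_id` (orthogroup), `strain_id`, sample
#'   columns; counts are conserved exactly per strain and sample.
#' @export
aggregate_by_og <- function(per_strain, samples, og_map = NULL) {
  smp <- intersect(names(per_strain), samples$sample)
  if (is.null(og_map)) {
    stopifnot("orthogroup_id" %in% names(per_strain))
    og_map <- per_strain[, c("gene_id", "orthogroup_id")]
  }
  tbl <- per_strain |>
    dplyr::select(dplyr::all_of(c("gene_id", "strain_id", smp))) |>
    dplyr::left_join(og_map, by = "gene_id")
  tbl$orthogroup_id[is.na(tbl$orthogroup_id)] <-
    paste0("OG_single_", tbl$gene_id[is.na(tbl$orthogroup_id)])
  tbl |>
    dplyr::group_by(feature_id = .data$orthogroup_id, .data$strain_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(smp), sum), .groups = "drop")
}

#' Community-scale orthogroup differential expression
#'
#' Pools transcript counts of each orthogroup across all bacterial strains of
#' the community (the unfiltered table, interstrain duplicates included) and
#' performs a single NB differential-expression analysis on the summed
#' matrix. This captures community-level responses that per-strain tests can
#' miss -- or cancel, when strains respond in opposite directions.
#'
#' @param community Unfiltered community count tibble from
#'   [resolve_duplicates()] (needs `kingdom`, `orthogroup_id`).
#' @param samples Sample metadata tibble.
#' @param og_map Optional alternative gene -> group map.
#' @param kingdom_filter Features to keep (default `"bacteria"`).
#' @param ... Passed to [run_de()].
#' @return A `syncom_de` object over orthogroups.
#' @export
community_og_de <- function(community, samples, og_map = NULL,
                            kingdom_filter = "bacteria", ...) {
  sub <- if ("kingdom" %in% names(community)) {
    community[community$kingdom %in% kingdom_filter, ]
  } else community
  smp <- intersect(names(sub), samples$sample)
  if (is.null(og_map)) {
    stopifnot("orthogroup_id" %in% names(sub))
    og_map <- sub[, c("gene_id", "orthogroup_id")]
  }
  pooled <- sub |>
    dplyr::select(dplyr::all_of(c("gene_id", smp))) |>
    dplyr::left_join(og_map, by = "gene_id")
  pooled$orthogroup_id[is.na(pooled$orthogroup_id)] <-
    paste0("OG_single_", pooled$gene_id[is.na(pooled$orthogroup_id)])
  pooled <- pooled |>
    dplyr::group_by(feature_id = .data$orthogroup_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(smp), sum), .groups = "drop")
  run_de(pooled, samples, ...)
}

#' Cumulative-log2FC ranking of conserved orthogroup responses
#'
#' The conserved-response statistic: for each orthogroup, the sum over focal
#' strains of its shrunken per-strain log2 fold change (orthogroups untested
#' or absent in a strain contribute 0). Orthogroups are ranked by this
#' cumulative log2FC, descending; ties are broken by community-scale log2FC
#' and then by orthogroup id.
#'
#' @param strain_og_de A `strain_de_set` from [run_per_strain_de()] on
#'   orthogroup counts for the focal strains.
#' @param community_de Optional `syncom_de` from [community_og_de()]; its
#'   log2FC and padj annotate the table and break ties.
#' @param top_k Size of the reported top slice (default 200; the full ranked
#'   table is kept in the `full` attribute).
#' @return Tibble of the top `top_k` orthogroups: `orthogroup_id`,
#'   `cumulative_log2fc`, `n_strains_tested`, `n_strains_deg`,
#'   `community_log2fc`, `community_padj`, `rank`; full table in
#'   `attr(, "full")`.
#' @export
cumulative_lfc_ranking <- function(strain_og_de, community_de = NULL,
                                   top_k = 200) {
  long <- tidy(strain_og_de)
  long <- long[!is.na(long$feature_id), ]
  agg <- long |>
    dplyr::group_by(orthogroup_id = .data$feature_id) |>
    dplyr::summarise(
      cumulative_log2fc = sum(.data$log2fc_shrunk[.data$tested], na.rm = TRUE),
      n_strains_tested = sum(.data$tested),
      n_strains_deg = sum(.data$deg, na.rm = TRUE),
      .groups = "drop")

  if (!is.null(community_de)) {
    cm <- community_de$result
    agg <- dplyr::left_join(
      agg,
      tibble::tibble(orthogroup_id = cm$feature_id,
                     community_log2fc = cm$log2fc_shrunk,
                     community_padj = cm$padj),
      by = "orthogroup_id")
  } else {
    agg$community_log2fc <- NA_real_
    agg$community_padj <- NA_real_
  }

  key2 <- ifelse(is.na(agg$community_log2fc), -Inf, agg$community_log2fc)
  ord <- order(-agg$cumulative_log2fc, -key2, agg$orthogroup_id)
  agg <- agg[ord, ]
  agg$rank <- seq_len(nrow(agg))

  if (top_k > nrow(agg)) {
    warning("top_k = ", top_k, " exceeds the ", nrow(agg),
            " available orthogroups; returning all", call. = FALSE)
    top_k <- nrow(agg)
  }
  out <- agg[seq_len(top_k), ]
  attr(out, "full") <- agg
  out
}
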