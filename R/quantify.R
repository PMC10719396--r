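#' Resolve identity-class counts into per-strain and community count tables
#'
#' Applies the duplicate rule of strain-resolved metatranscriptomics:
#' genes with identical sequences in several strains cannot be attributed to
#' a strain, so classes with scope `interstrain_duplicate` or `mixed` are
#' removed from per-strain tables, while identical paralogs within one strain
#' are kept and counted once under the class representative. Community-scale
#' tables are left unfiltered: every class count is attributed to its
#' representative gene.
#'
#' @param class_counts Tibble of class-level counts (`sample`, `class_id`,
#'   `count`), e.g. `assign_reads(...)$counts`.
#' @param classes An [build_identity_classes()] tibble covering the catalog.
#' @return List with two wide count tibbles (`gene_id`, feature metadata,
#'   then one column per sample): `per_strain` (interstrain classes removed)
#'   and `community` (all classes).
#' @export
resolve_duplicates <- function(class_counts, classes) {
  stopifnot(all(c("sample", "class_id", "count") %in% names(class_counts)))
  unknown <- setdiff(class_counts$class_id, classes$class_id)
  if (length(unknown) > 0L) {
    stop("class counts reference unknown classes: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  reps <- classes[classes$is_representative, ]
  meta_cols <- intersect(c("strain_id", "kingdom", "orthogroup_id", "length", "scope"),
                         names(reps))

  widen <- function(keep_classes) {
    sub <- class_counts[class_counts$class_id %in% keep_classes$class_id, ]
    wide <- sub |>
      dplyr::group_by(.data$class_id, .data$sample) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "count",
                         values_fill = 0)
    out <- dplyr::left_join(
      keep_classes[, c("gene_id", "class_id", meta_cols)],
      wide, by = "class_id")
    smp <- setdiff(names(out), c("gene_id", "class_id", meta_cols))
    for (s in smp) out[[s]][is.na(out[[s]])] <- 0
    dplyr::select(out, -"class_id") |> dplyr::rename(gene_id = "gene_id")
  }

  per_strain <- widen(reps[!reps$scope %in% c("interstrain_duplicate", "mixed"), ])
  community <- widen(reps)
  list(per_strain = per_strain, community = community)
}

count_cols <- function(counts) {
  setdiff(names(counts), c("gene_id", "orthogroup_id", "strain_id", "kingdom",
                           "length", "scope", "feature_id"))
}

#' RNA-based strain relative abundance profile
#'
#' Percentage of each sample's microbial reads attributed to each strain;
#' host features are excluded from the denominator.
#'
#' When the identity-class table is supplied, reads of interstrain-duplicate
#' (and mixed) classes -- which cannot be attributed to one strain by
#' sequence -- are split across the member strains in proportion to each
#' strain's unambiguous read mass in that sample (equally when no member has
#' unambiguous reads), the abundance-weighted attribution an EM-based
#' quantifier converges to. Without `classes`, each class count sits wholly
#' on its representative gene's strain.
#'
#' @param community Community count tibble from [resolve_duplicates()] (needs
#'   `strain_id` and, if host genes are present, `kingdom`).
#' @param classes Optional [build_identity_classes()] tibble for
#'   duplicate-aware strain attribution.
#' @return Abundance-profile tibble: `strain_id`, `sample`, `ra` (percent,
#'   summing to 100 per sample), `reads`, `basis = "RNA"`. Samples with zero
#'   microbial reads are flagged with `ra = NA` and a warning.
#' @export
strain_relative_abundance <- function(community, classes = NULL) {
  stopifnot("strain_id" %in% names(community))
  microbial <- if ("kingdom" %in% names(community)) {
    community[community$kingdom != "host", ]
  } else community
  smp <- count_cols(microbial)
  long <- microbial |>
    dplyr::select(dplyr::all_of(c("gene_id", "strain_id", smp))) |>
    tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample", values_to = "count")

  if (!is.null(classes)) {
    shared <- classes[classes$scope %in% c("interstrain_duplicate", "mixed"), ]
    if (nrow(shared) > 0L) {
      # unambiguous strain mass per sample
      amb_genes <- shared$gene_id
      base <- long[!long$gene_id %in% amb_genes, ] |>
        dplyr::group_by(.data$strain_id, .data$sample) |>
        dplyr::summarise(w = sum(.data$count), .groups = "drop")
      # class counts sit on the representative row
      amb <- long[long$gene_id %in% shared$gene_id[shared$is_representative] &
                    long$count > 0, ]
      amb <- dplyr::left_join(
        amb, shared[shared$is_representative, c("gene_id", "class_id")],
        by = "gene_id")
      members <- dplyr::distinct(shared[, c("class_id", "strain_id")])
      redis <- amb |>
        dplyr::select("class_id", "sample", "count") |>
        dplyr::left_join(members, by = "class_id",
                         relationship = "many-to-many") |>
        dplyr::left_join(base, by = c("strain_id", "sample")) |>
        dplyr::mutate(w = ifelse(is.na(.data$w), 0, .data$w)) |>
        dplyr::group_by(.data$class_id, .data$sample) |>
        dplyr::mutate(share = ifelse(sum(.data$w) > 0, .data$w / sum(.data$w),
                                     1 / dplyr::n())) |>
        dplyr::ungroup() |>
        dplyr::mutate(count = .data$count * .data$share)
      long <- dplyr::bind_rows(
        long[!long$gene_id %in% amb_genes, ],
        redis[, c("strain_id", "sample", "count")])
    }
  }

  long <- long |>
    dplyr::group_by(.data$strain_id, .data$sample) |>
    dplyr::summarise(reads = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(total = sum(.data$reads)) |>
    dplyr::ungroup()
  if (any(long$total == 0)) {
    warning("sample(s) with zero microbial reads: ",
            paste(unique(long$sample[long$total == 0]), collapse = ", "),
            call. = FALSE)
  }
  long$ra <- ifelse(long$total > 0, 100 * long$reads / long$total, NA_real_)
  long$basis <- "RNA"
  dplyr::select(long, "strain_id", "sample", "reads", "ra", "basis")
}

#' Per-compartment strain detection calls
#'
#' A strain is detected in a compartment when at least one replicate carries
#' at least `detection_min` reads for it (fractional EM counts are compared
#' against the same threshold, preserving the at-least-one-read meaning).
#'
#' @param community Community count tibble from [resolve_duplicates()].
#' @param samples Sample metadata tibble (`sample`, `compartment`).
#' @param detection_min Minimum per-replicate count (default 1.0).
#' @return Tibble: `strain_id`, `compartment`, `detected`.
#' @export
detect_strains <- function(community, samples, detection_min = 1.0) {
  microbial <- if ("kingdom" %in% names(community)) {
    community[community$kingdom != "host", ]
  } else community
  smp <- intersect(count_cols(microbial), samples$sample)
  microbial |>
    dplyr::select(dplyr::all_of(c("strain_id", smp))) |>
    tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample", values_to = "count") |>
    dplyr::left_join(samples[, c("sample", "compartment")], by = "sample") |>
    dplyr::group_by(.data$strain_id, .data$compartment, .data$sample) |>
    dplyr::summarise(reads = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$strain_id, .data$compartment) |>
    dplyr::summarise(detected = any(.data$reads >= detection_min), .groups = "drop")
}

#' Per-strain, per-compartment gene detection counts
#'
#' @param per_strain Per-strain count tibble from [resolve_duplicates()].
#' @param samples Sample metadata tibble.
#' @param detection_min Minimum count in some replicate for a gene to be
#'   called detected.
#' @return Tibble: `strain_id`, `compartment`, `n_genes_detected`.
#' @export
count_detected_genes <- function(per_strain, samples, detection_min = 1.0) {
  smp <- intersect(count_cols(per_strain), samples$sample)
  per_strain |>
    dplyr::select(dplyr::all_of(c("gene_id", "strain_id", smp))) |>
    tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample", values_to = "count") |>
    dplyr::left_join(samples[, c("sample", "compartment")], by = "sample") |>
    dplyr::group_by(.data$strain_id, .data$gene_id, .data$compartment) |>
    dplyr::summarise(detected = any(.data$count >= detection_min), .groups = "drop") |>
    dplyr::group_by(.data$strain_id, .data$compartment) |>
    dplyr::summarise(n_genes_detected = sum(.data$detected), .groups = "drop")
}

#' Select focal strains for per-strain analyses
#'
#' Eligible strains have more than `min_genes` genes detected in both
#' compartments; eligible strains are ranked by mean root relative abundance
#' and the top `top_n` are returned.
#'
#' @param per_strain Per-strain count tibble from [resolve_duplicates()].
#' @param samples Sample metadata tibble.
#' @param profile RNA abundance profile from [strain_relative_abundance()].
#' @param min_genes Detection threshold on genes per compartment
#'   (default 1000, matching deep community catalogs; lower it for small
#'   simulations).
#' @param top_n Maximum number of focal strains (default 20).
#' @param detection_min Per-replicate count for a gene to count as detected.
#' @return Character vector of focal strain ids, ranked by mean root RA.
#' @export
select_focal_strains <- function(per_strain, samples, profile,
                                 min_genes = 1000, top_n = 20,
                                 detection_min = 1.0) {
  det <- count_detected_genes(per_strain, samples, detection_min)
  eligible <- det |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$compartment[.data$n_genes_detected > min_genes]) == 2L,
                     .groups = "drop") |>
    dplyr::filter(.data$ok)
  if (nrow(eligible) == 0L) return(character(0))
  root_samples <- samples$sample[samples$compartment == "root"]
  rank_tbl <- profile |>
    dplyr::filter(.data$sample %in% root_samples,
                  .data$strain_id %in% eligible$strain_id) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(mean_root_ra = mean(.data$ra), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_root_ra), .data$strain_id)
  utils::head(rank_tbl$strain_id, top_n)
}

#' Transcripts-per-million within each strain's gene set
#'
#' \eqn{TPM_{ij} = 10^6 (k_{ij}/L_i) / \sum_i (k_{ij}/L_i)}, computed per
#' strain per sample.
#'
#' @param per_strain Per-strain count tibble (needs `strain_id`, `length`).
#' @return Tibble in the same layout with counts replaced by TPM values;
#'   per-strain columns sum to 1e6 (all-zero columns stay zero and are
#'   flagged with a warning).
#' @export
compute_tpm <- function(per_strain) {
  stopifnot(all(c("strain_id", "length") %in% names(per_strain)))
  if (any(per_strain$length <= 0)) stop("gene lengths must be positive", call. = FALSE)
  smp <- count_cols(per_strain)
  out <- per_strain
  flagged <- character(0)
  for (s in unique(per_strain$strain_id)) {
    rows <- which(per_strain$strain_id == s)
    for (j in smp) {
      rate <- per_strain[[j]][rows] / per_strain$length[rows]
      tot <- sum(rate)
      if (tot == 0) {
        flagged <- c(flagged, paste0(s, "/", j))
        out[[j]][rows] <- 0
      } else {
        out[[j]][rows] <- 1e6 * rate / tot
      }
    }
  }
  if (length(flagged) > 0L) {
    warning("all-zero strain/sample column(s): ",
            paste(utils::head(flagged, 5), collapse = ", "), call. = FALSE)
  }
  out
}
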