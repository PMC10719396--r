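#' Partition a gene catalog into exact-sequence identity classes
#'
#' Multi-genome catalogs contain byte-identical coding sequences, both across
#' strains (conserved genes carried by several genomes) and within one strain
#' (identical paralogs). Reads can never distinguish members of such a class,
#' so the class -- not the gene -- is the unit at which reads are counted and
#' at which the per-strain duplicate filter operates.
#'
#' Scope labels: `unique` (one member), `within_strain_paralog` (>= 2 members,
#' all in one strain), `interstrain_duplicate` (members span >= 2 strains, one
#' per strain), `mixed` (spans >= 2 strains with paralogy inside at least one
#' of them). Per-strain analyses drop `interstrain_duplicate` and `mixed`
#' classes; community-scale analyses keep everything.
#'
#' @param catalog Catalog tibble (needs `gene_id`, `strain_id`, `sequence`;
#'   `kingdom`, `orthogroup_id`, `length` are carried through when present).
#' @return A tibble of class `identity_classes`, one row per catalog gene:
#'   `gene_id`, `strain_id`, `class_id`, `scope`, `representative` (the
#'   lexicographically smallest member gene_id), `is_representative`, plus any
#'   carried metadata columns.
#' @export
build_identity_classes <- function(catalog) {
  stopifnot(nrow(catalog) > 0, all(c("gene_id", "strain_id", "sequence") %in% names(catalog)))
  if (anyDuplicated(catalog$gene_id)) stop("gene_ids must be unique", call. = FALSE)

  grp <- match(catalog$sequence, catalog$sequence)  # first occurrence index
  reps <- vapply(split(catalog$gene_id, grp), function(g) min(g), character(1))
  n_strain <- vapply(split(catalog$strain_id, grp), function(s) length(unique(s)), integer(1))
  n_member <- vapply(split(catalog$gene_id, grp), length, integer(1))

  scope <- ifelse(n_member == 1L, "unique",
           ifelse(n_strain == 1L, "within_strain_paralog",
           ifelse(n_member == n_strain, "interstrain_duplicate", "mixed")))

  # deterministic ids in representative order
  ord <- order(reps)
  class_id <- stats::setNames(sprintf("IC%06d", order(ord)), names(reps))

  key <- as.character(grp)
  out <- tibble::tibble(
    gene_id = catalog$gene_id,
    strain_id = catalog$strain_id,
    class_id = unname(class_id[key]),
    scope = unname(scope[key]),
    representative = unname(reps[key])
  )
  out$is_representative <- out$gene_id == out$representative
  for (col in intersect(c("kingdom", "orthogroup_id", "length"), names(catalog))) {
    out[[col]] <- catalog[[col]]
  }
  class(out) <- c("identity_classes", class(out))
  out
}

#' Summarize identity classes (one row per class)
#' @param classes Output of [build_identity_classes()].
#' @return Tibble: `class_id`, `representative`, `scope`, `n_members`,
#'   `n_strains`.
#' @export
summarize_identity_classes <- function(classes) {
  classes |>
    dplyr::group_by(.data$class_id, .data$representative, .data$scope) |>
    dplyr::summarise(n_members = dplyr::n(),
                     n_strains = dplyr::n_distinct(.data$strain_id),
                     .groups = "drop") |>
    dplyr::arrange(.data$class_id)
}
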