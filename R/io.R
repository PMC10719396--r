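#' Write a gene catalog to FASTA plus annotation TSV
#'
#' FASTA headers are `gene_id|strain_id`; the annotation TSV has columns
#' `gene_id`, `strain_id`, `kingdom`, `orthogroup_id`, `cog_category`,
#' `go_terms` (semicolon-joined).
#'
#' @param catalog Catalog tibble.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_catalog <- function(catalog, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- paste(catalog$gene_id, catalog$strain_id, sep = "|")
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- catalog[, c("gene_id", "strain_id", "kingdom", "orthogroup_id",
                     "cog_category", "go_terms")]
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}

#' Read a gene catalog from FASTA plus annotation TSV
#'
#' @param fasta_path FASTA of coding sequences with `gene_id|strain_id`
#'   headers.
#' @param annotation_path Annotation TSV as written by [write_catalog()].
#' @return Catalog tibble.
#' @export
read_catalog <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[`, character(1), 1)
  ann <- tibble::as_tibble(utils::read.table(annotation_path, sep = "\t",
                                             header = TRUE,
                                             colClasses = "character"))
  ann$go_terms[is.na(ann$go_terms)] <- ""
  tbl <- tibble::tibble(gene_id = ids, sequence = unname(as.character(seqs)),
                        length = Biostrings::width(seqs))
  out <- dplyr::left_join(ann, tbl, by = "gene_id")
  dplyr::relocate(out, "gene_id", "strain_id", "kingdom", "sequence",
                  "length", "orthogroup_id", "cog_category", "go_terms")
}

#' Write / read a wide count table as TSV
#' @param counts Wide count tibble.
#' @param path File path.
#' @return `write_counts_tsv` the path (invisibly); `read_counts_tsv` a
#'   tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
}

#' Write / read sample metadata TSV (`sample`, `compartment`, `replicate`)
#' @param samples Sample metadata tibble.
#' @param path File path.
#' @export
write_samples_tsv <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_tsv
#' @export
read_samples_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE,
                                      colClasses = c(sample = "character")))
}
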