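revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

kmerize <- function(seqs, k) {
  # all k-mers of each sequence, flattened, with the originating element index
  n <- nchar(seqs) - k + 1L
  stopifnot(all(n >= 1L))
  idx <- rep.int(seq_along(seqs), n)
  starts <- sequence(n)
  list(kmer = substring(seqs[idx], starts, starts + k - 1L), idx = idx)
}

#' Build a duplicate-aware k-mer index over a gene catalog
#'
#' Indexes every k-mer of every identity-class sequence (class members are
#' byte-identical, so the representative sequence stands for the class). The
#' index keeps duplicates: a k-mer shared by identical genes in several
#' strains maps to their single shared identity class, never arbitrarily to
#' one gene.
#'
#' @param catalog Catalog tibble (see [build_identity_classes()]).
#' @param k K-mer size; must satisfy `11 <= k < min(gene length)`.
#' @param classes Optional precomputed [build_identity_classes()] result.
#' @return An object of class `kmer_index`: the k, the unique k-mer table with
#'   the set of identity classes each k-mer occurs in, and the class table.
#' @export
build_kmer_index <- function(catalog, k = 31L, classes = NULL) {
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11", call. = FALSE)
  if (k >= min(nchar(catalog$sequence))) {
    stop("k must be smaller than the shortest gene (",
         min(nchar(catalog$sequence)), " bp)", call. = FALSE)
  }
  if (is.null(classes)) classes <- build_identity_classes(catalog)

  reps <- classes[classes$is_representative, ]
  seq_of <- stats::setNames(catalog$sequence, catalog$gene_id)
  rep_seqs <- unname(seq_of[reps$gene_id])

  km <- kmerize(rep_seqs, k)
  dt <- data.table::data.table(kmer = km$kmer, cls = km$idx)
  dt <- unique(dt)
  agg <- dt[, list(set = list(cls)), by = "kmer"]

  structure(list(
    k = k,
    kmers = agg$kmer,
    sets = agg$set,
    class_id = reps$class_id,
    representative = reps$gene_id,
    class_length = nchar(rep_seqs),
    classes = classes
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, "; ", length(x$kmers), " distinct k-mers over ",
      length(x$class_id), " identity classes\n", sep = "")
  invisible(x)
}

#' Look up the identity classes containing a k-mer
#'
#' Queries are strand-agnostic: the k-mer and its reverse complement are both
#' checked.
#'
#' @param index A [build_kmer_index()] object.
#' @param kmer Character vector of k-mers (each of length `index$k`).
#' @return List (one element per query) of class_id character vectors; empty
#'   when the k-mer occurs nowhere in the catalog.
#' @export
kmer_lookup <- function(index, kmer) {
  stopifnot(all(nchar(kmer) == index$k))
  hit_f <- match(kmer, index$kmers)
  hit_r <- match(revcomp_chr(kmer), index$kmers)
  lapply(seq_along(kmer), function(i) {
    s <- unique(c(if (!is.na(hit_f[i])) index$sets[[hit_f[i]]],
                  if (!is.na(hit_r[i])) index$sets[[hit_r[i]]]))
    index$class_id[s]
  })
}
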