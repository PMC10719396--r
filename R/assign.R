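#' Assign reads to identity classes by k-mer compatibility
#'
#' A read's compatibility set is the intersection, over all of its k-mers, of
#' the identity-class sets those k-mers occur in; an empty intersection leaves
#' the read unassigned. Orientation is handled per read: the forward sequence
#' is tried first and the reverse complement is tried for reads the forward
#' orientation cannot fully place. Reads whose compatibility set has one
#' class carry unambiguous evidence; multi-class reads are either dropped
#' (`mode = "unique_only"`) or fractionally distributed by an
#' expectation-maximization iteration over equivalence classes
#' (`mode = "em"`): class weights start uniform and are updated as
#' \eqn{c_i \leftarrow \sum_{reads} w_i / \sum_{j \in compat} w_j} until the
#' largest count change is below `tol` or `max_iter` iterations.
#'
#' @param index A [build_kmer_index()] object.
#' @param reads Tibble with columns `sample`, `read_id`, `sequence` (e.g.
#'   from [simulate_reads()] or [read_reads_fastq()]).
#' @param mode `"em"` (default) or `"unique_only"`.
#' @param tol EM convergence tolerance on the max absolute count change.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `read_assignment`: `counts` (tibble: `sample`,
#'   `class_id`, `representative`, `count`), `ec_counts` (tibble: `sample`,
#'   `ec` -- the sorted compatible class ids joined by `;` -- and `count`),
#'   `unassigned` (tibble: `sample`, `n_unassigned`, `n_reads`), `mode`, `k`.
#' @export
assign_reads <- function(index, reads, mode = c("em", "unique_only"),
                         tol = 1e-6, max_iter = 100L) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample", "read_id", "sequence") %in% names(reads)))
  k <- index$k
  n_class <- length(index$class_id)

  counts_out <- list(); ec_out <- list(); un_out <- list()
  for (smp in unique(reads$sample)) {
    seqs <- reads$sequence[reads$sample == smp]
    n_reads <- length(seqs)
    short <- nchar(seqs) < k
    if (any(short)) {
      warning(sum(short), " read(s) shorter than k=", k, " in sample ", smp,
              " counted as unassigned", call. = FALSE)
    }
    seqs <- seqs[!short]

    # identical reads share one compatibility computation
    useq <- unique(seqs)
    umult <- tabulate(match(seqs, useq), length(useq))
    pairs <- compat_pairs(index, useq)

    n_compat <- tabulate(pairs$read, length(useq))
    n_unassigned <- sum(short) + sum(umult[n_compat == 0L])
    pairs$weight <- umult[pairs$read]

    singles <- pairs[n_compat[pairs$read] == 1L, ]
    multis <- pairs[n_compat[pairs$read] > 1L, ]

    base <- numeric(n_class)
    if (nrow(singles) > 0L) {
      agg <- rowsum(singles$weight, singles$cls)
      base[as.integer(rownames(agg))] <- agg[, 1]
    }

    ec_sets <- list(); n_ec <- numeric(0)
    if (nrow(multis) > 0L) {
      multis <- multis[order(multis$read, multis$cls), ]
      grp <- split(multis$cls, multis$read)
      key <- vapply(grp, paste, character(1), collapse = ";")
      w_read <- vapply(split(multis$weight, multis$read), `[`, numeric(1), 1)
      tab <- rowsum(w_read, key)
      ec_sets <- lapply(strsplit(rownames(tab), ";", fixed = TRUE), as.integer)
      n_ec <- tab[, 1]
    }

    cls_counts <- switch(mode,
      unique_only = {
        n_unassigned <- n_unassigned + sum(n_ec)
        base
      },
      em = em_counts(ec_sets, n_ec, base, tol, max_iter)
    )

    nz <- which(cls_counts > 0)
    if (length(nz) > 0L) {
      counts_out[[smp]] <- tibble::tibble(
        sample = smp,
        class_id = index$class_id[nz],
        representative = index$representative[nz],
        count = cls_counts[nz]
      )
    }
    single_cls <- sort(unique(singles$cls))
    ec_out[[smp]] <- tibble::tibble(
      sample = smp,
      ec = c(index$class_id[single_cls],
             vapply(ec_sets, function(s) paste(index$class_id[s], collapse = ";"),
                    character(1))),
      count = c(base[single_cls], unname(n_ec))
    )
    un_out[[smp]] <- tibble::tibble(sample = smp, n_unassigned = n_unassigned,
                                    n_reads = n_reads)
  }

  structure(list(
    counts = dplyr::bind_rows(counts_out),
    ec_counts = dplyr::bind_rows(ec_out),
    unassigned = dplyr::bind_rows(un_out),
    mode = mode, k = k
  ), class = "read_assignment")
}

# full-compatibility (read index, class index) pairs for a set of sequences,
# trying the reverse complement for reads the forward orientation cannot
# place entirely
compat_pairs <- function(index, seqs) {
  if (length(seqs) == 0L) {
    return(data.table::data.table(read = integer(0), cls = integer(0)))
  }
  pairs <- compat_pairs_one(index, seqs, seq_along(seqs))
  placed <- unique(pairs$read)
  miss <- setdiff(seq_along(seqs), placed)
  if (length(miss) > 0L) {
    rc <- compat_pairs_one(index, revcomp_chr(seqs[miss]), miss)
    pairs <- rbind(pairs, rc)
  }
  pairs
}

compat_pairs_one <- function(index, seqs, read_idx) {
  k <- index$k
  km <- kmerize(seqs, k)
  hit <- match(km$kmer, index$kmers)
  n_pos <- nchar(seqs) - k + 1L
  bad <- unique(km$idx[is.na(hit)])
  keep <- !(km$idx %in% bad)
  if (!any(keep)) {
    return(data.table::data.table(read = integer(0), cls = integer(0)))
  }
  sets <- index$sets[hit[keep]]
  dt <- data.table::data.table(
    local = rep.int(km$idx[keep], lengths(sets)),
    cls = unlist(sets, use.names = FALSE)
  )
  agg <- dt[, list(n = .N), by = c("local", "cls")]
  full <- agg[agg$n == n_pos[agg$local], ]
  data.table::data.table(read = read_idx[full$local], cls = full$cls)
}

# EM over ambiguous equivalence classes on top of the fixed uniquely-assigned
# base counts; returns per-class fractional counts
em_counts <- function(ec_sets, n_ec, base, tol = 1e-6, max_iter = 100L) {
  if (length(ec_sets) == 0L) return(base)
  lens <- lengths(ec_sets)
  flat_cls <- unlist(ec_sets, use.names = FALSE)
  flat_ec <- rep.int(seq_along(ec_sets), lens)
  n_class <- length(base)
  w <- rep(1, n_class)
  cls_counts <- base
  for (iter in seq_len(max_iter)) {
    num <- w[flat_cls]
    denom <- rowsum(num, flat_ec)[, 1]
    contrib <- n_ec[flat_ec] * num / denom[flat_ec]
    new_counts <- base
    agg <- rowsum(contrib, flat_cls)
    new_counts[as.integer(rownames(agg))] <-
      new_counts[as.integer(rownames(agg))] + agg[, 1]
    delta <- max(abs(new_counts - cls_counts))
    cls_counts <- new_counts
    w <- pmax(cls_counts, 1e-12)
    if (delta < tol) break
  }
  cls_counts
}

#' @export
print.read_assignment <- function(x, ...) {
  tot <- sum(x$unassigned$n_reads)
  cat("<read_assignment> mode=", x$mode, "; ", tot, " reads, ",
      sum(x$unassigned$n_unassigned), " unassigned (",
      nrow(x$counts), " class-sample count rows)\n", sep = "")
  invisible(x)
}
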