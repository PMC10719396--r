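#' Emit error-free reads from a simulated count table
#'
#' For every gene-sample count c, draws exactly c uniform-position, error-free
#' substrings of the gene's coding sequence. Read names encode the sample and
#' the true origin gene, so assignment accuracy can be scored against truth.
#'
#' @param catalog Catalog tibble from [simulate_catalog()].
#' @param counts Count tibble (`gene_id` + sample columns) from
#'   [simulate_expression()].
#' @param config The [sim_config()] in use; `read_length` and `seed` matter.
#' @return Tibble with `sample`, `read_id`, `true_gene`, `sequence`.
#' @export
simulate_reads <- function(catalog, counts, config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed + 2L)
  rl <- cfg$read_length

  too_short <- catalog$length < rl
  if (any(too_short)) {
    bad <- catalog$gene_id[which(too_short)[1]]
    stop("read length ", rl, " exceeds the length of gene ", bad, call. = FALSE)
  }

  seq_of <- stats::setNames(catalog$sequence, catalog$gene_id)
  len_of <- stats::setNames(catalog$length, catalog$gene_id)
  sample_cols <- setdiff(names(counts), "gene_id")

  out <- vector("list", length(sample_cols))
  for (i in seq_along(sample_cols)) {
    smp <- sample_cols[i]
    cnt <- round(counts[[smp]])
    keep <- cnt > 0
    genes <- rep(counts$gene_id[keep], cnt[keep])
    if (length(genes) == 0L) {
      out[[i]] <- tibble::tibble(sample = character(0), read_id = character(0),
                                 true_gene = character(0), sequence = character(0))
      next
    }
    max_start <- len_of[genes] - rl + 1L
    starts <- floor(stats::runif(length(genes)) * max_start) + 1L
    reads <- substring(seq_of[genes], starts, starts + rl - 1L)
    out[[i]] <- tibble::tibble(
      sample = smp,
      read_id = sprintf("%s_r%07d|%s", smp, seq_along(genes), genes),
      true_gene = genes,
      sequence = unname(reads)
    )
  }
  dplyr::bind_rows(out)
}

#' Write simulated reads to per-sample FASTQ files
#'
#' @param reads Tibble from [simulate_reads()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written (one per sample; a
#'   sample with zero reads yields a valid empty file).
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (smp in unique(reads$sample)) {
    sub <- reads[reads$sample == smp, ]
    path <- file.path(dir, paste0(smp, ".fastq"))
    if (nrow(sub) == 0L) {
      file.create(path)
    } else {
      qual <- strrep("I", nchar(sub$sequence))
      writeLines(paste0("@", sub$read_id, "\n", sub$sequence, "\n+\n", qual), path,
                 sep = "\n")
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-sample FASTQ files into the reads tibble layout
#'
#' @param paths FASTQ file paths; the sample name is the file base name.
#' @return Tibble with `sample`, `read_id`, `sequence`.
#' @export
read_reads_fastq <- function(paths) {
  out <- lapply(paths, function(p) {
    smp <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(p))
    if (file.size(p) == 0) {
      return(tibble::tibble(sample = character(0), read_id = character(0),
                            sequence = character(0)))
    }
    sr <- Biostrings::readDNAStringSet(p, format = "fastq")
    tibble::tibble(sample = smp, read_id = names(sr),
                   sequence = unname(as.character(sr)))
  })
  dplyr::bind_rows(out)
}

#' Simulate a DNA-based (amplicon) strain abundance profile
#'
#' Draws amplicon read counts per strain and sample from a multinomial
#' centred on the true compartment relative abundances, after applying a
#' per-strain per-sample detection dropout that emulates the lower
#' sensitivity of amplicon profiling relative to deep RNA-seq read mapping.
#'
#' @param truth Truth list from [simulate_expression()] (uses `strain_ra`).
#' @param config The [sim_config()]; `amplicon_reads`, `amplicon_dropout`,
#'   `n_replicates` and `seed` matter.
#' @return Abundance-profile tibble: `strain_id`, `sample`, `compartment`,
#'   `reads`, `ra` (percent; sums to 100 over detected strains per sample),
#'   `basis = "DNA"`.
#' @export
simulate_amplicon <- function(truth, config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed + 3L)
  out <- list()
  for (cmp in c("root", "matrix")) {
    ra <- truth$strain_ra[truth$strain_ra$compartment == cmp, ]
    for (r in seq_len(cfg$n_replicates)) {
      detected <- stats::runif(nrow(ra)) >= cfg$amplicon_dropout
      p <- ra$ra * detected
      reads <- if (sum(p) > 0) {
        as.vector(stats::rmultinom(1, size = cfg$amplicon_reads, prob = p / sum(p)))
      } else rep(0L, nrow(ra))
      tot <- sum(reads)
      out[[length(out) + 1L]] <- tibble::tibble(
        strain_id = ra$strain_id,
        sample = sprintf("%s_%d", cmp, r),
        compartment = cmp,
        reads = reads,
        ra = if (tot > 0) 100 * reads / tot else NA_real_,
        basis = "DNA"
      )
    }
  }
  dplyr::bind_rows(out)
}
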