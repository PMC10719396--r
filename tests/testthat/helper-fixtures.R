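# small in-code fixtures shared across test files

tiny_config <- function(...) {
  args <- utils::modifyList(list(
    n_strains = 3, genes_per_strain = 20, n_orthogroups = 12,
    frac_interstrain_duplicate = 0.1, frac_within_strain_paralog = 0.1,
    gene_length_range = c(200L, 400L), k = 21L, read_length = 50L,
    n_host_genes = 5, reads_per_sample = 2000, seed = 101
  ), list(...))
  do.call(sim_config, args)
}

# deterministic random DNA of given lengths under a local seed
fixture_dna <- function(lengths, seed = 1) {
  withr::with_seed(seed, vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
}

# hand-built catalog: strains/sequences given explicitly
manual_catalog <- function(gene_id, strain_id, sequence,
                           kingdom = "bacteria", orthogroup_id = NULL,
                           cog_category = "C", go_terms = "") {
  tibble::tibble(
    gene_id = gene_id, strain_id = strain_id, kingdom = kingdom,
    sequence = sequence, length = nchar(sequence),
    orthogroup_id = orthogroup_id %||% paste0("OG_", gene_id),
    cog_category = cog_category, go_terms = go_terms
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wide count tibble from a matrix with root_/matrix_ samples
counts_from_matrix <- function(m, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("g%04d", seq_len(nrow(m)))
  out <- tibble::tibble(gene_id = gene_ids)
  for (j in seq_len(ncol(m))) out[[colnames(m)[j]]] <- m[, j]
  out
}

samples_3v3 <- function(n_rep = 3) {
  tibble::tibble(
    sample = c(sprintf("root_%d", seq_len(n_rep)),
               sprintf("matrix_%d", seq_len(n_rep))),
    compartment = rep(c("root", "matrix"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2)
  )
}

# NB count tables matching the generator's model, for DE calibration tests
nb_counts <- function(n_genes, beta = numeric(n_genes), n_rep = 3,
                      mean_log = log(50), mean_sd = 1.5,
                      a0 = 0.05, a1 = 1, seed = 1) {
  withr::with_seed(seed, {
    mu0 <- exp(stats::rnorm(n_genes, mean_log, mean_sd))
    smp <- samples_3v3(n_rep)
    m <- matrix(0, n_genes, nrow(smp), dimnames = list(NULL, smp$sample))
    for (j in seq_len(nrow(smp))) {
      mu <- mu0 * 2^(beta * (smp$compartment[j] == "root"))
      alpha <- a0 + a1 / mu
      m[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / alpha)
    }
    list(counts = counts_from_matrix(m), samples = smp, mu0 = mu0)
  })
}

# true class-level counts per sample from simulated reads (read-name oracle)
true_class_counts <- function(reads, classes) {
  cls <- classes$class_id[match(reads$true_gene, classes$gene_id)]
  out <- as.data.frame(table(sample = reads$sample, class_id = cls),
                       stringsAsFactors = FALSE)
  out[out$Freq > 0, ]
}

# L1 distance between estimated and true class counts, summed over samples
class_count_l1 <- function(est, truth) {
  key_e <- paste(est$sample, est$class_id)
  key_t <- paste(truth$sample, truth$class_id)
  keys <- union(key_e, key_t)
  e <- stats::setNames(rep(0, length(keys)), keys); e[key_e] <- est$count
  t <- stats::setNames(rep(0, length(keys)), keys); t[key_t] <- truth$Freq
  sum(abs(e - t))
}
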