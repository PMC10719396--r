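test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_interstrain_duplicate = 1.2), "fraction")
  expect_error(sim_config(n_strains = 1, frac_interstrain_duplicate = 0.2),
               "two strains")
  expect_error(sim_config(k = 400, gene_length_range = c(300, 500)), "k-mer")
  expect_error(sim_config(read_length = 20, k = 31), "read_length")
  expect_error(tiny_config(n_orthogroups = 25), "cannot exceed")
  expect_error(tiny_config(frac_within_strain_paralog = 0.9),
               "strain-specific genes")
})

test_that("zero-duplication catalogs have pairwise-distinct sequences", {
  cfg <- tiny_config(frac_interstrain_duplicate = 0,
                     frac_within_strain_paralog = 0)
  sim <- simulate_catalog(cfg)
  expect_equal(anyDuplicated(sim$catalog$sequence), 0L)
  expect_equal(nrow(sim$truth$identity), 0L)
})

test_that("interstrain duplicate placement hits the configured fraction", {
  # exact-sequence hashing oracle: genes in cross-strain identity classes
  cfg <- sim_config(n_strains = 2, genes_per_strain = 10, n_orthogroups = 8,
                    frac_interstrain_duplicate = 0.2,
                    frac_within_strain_paralog = 0,
                    gene_length_range = c(200L, 300L), k = 21L,
                    read_length = 50L, n_host_genes = 0, seed = 3)
  sim <- simulate_catalog(cfg)
  cat <- sim$catalog
  dup_genes <- split(cat$gene_id, cat$sequence)
  cross <- Filter(function(g) {
    length(unique(cat$strain_id[cat$gene_id %in% g])) > 1
  }, dup_genes[lengths(dup_genes) > 1])
  per_strain <- table(cat$strain_id[cat$gene_id %in% unlist(cross)])
  expect_equal(as.vector(per_strain), c(2, 2))
})

test_that("within-strain paralog pairs share sequence and orthogroup", {
  cfg <- tiny_config(frac_interstrain_duplicate = 0,
                     frac_within_strain_paralog = 0.2)
  sim <- simulate_catalog(cfg)
  par <- sim$truth$identity[sim$truth$identity$scope == "within_strain_paralog", ]
  expect_gt(nrow(par), 0)
  for (grp in split(par$gene_id, par$identity_group)) {
    rows <- sim$catalog[sim$catalog$gene_id %in% grp, ]
    expect_equal(length(unique(rows$strain_id)), 1L)
    expect_equal(length(unique(rows$sequence)), 1L)
    expect_equal(length(unique(rows$orthogroup_id)), 1L)
  }
})

test_that("the same seed reproduces the catalog and all downstream draws", {
  cfg <- tiny_config()
  a <- simulate_catalog(cfg); b <- simulate_catalog(cfg)
  expect_identical(a, b)
  ea <- simulate_expression(a$catalog, cfg)
  eb <- simulate_expression(b$catalog, cfg)
  expect_identical(ea, eb)
  expect_identical(simulate_reads(a$catalog, ea$counts, cfg),
                   simulate_reads(b$catalog, eb$counts, cfg))
  expect_identical(simulate_amplicon(ea$truth, cfg),
                   simulate_amplicon(eb$truth, cfg))
})

test_that("shared orthogroups span all strains and host genes stay separate", {
  cfg <- tiny_config()
  sim <- simulate_catalog(cfg)
  microbes <- sim$catalog[sim$catalog$kingdom != "host", ]
  shared <- sprintf("OG%05d", seq_len(cfg$n_orthogroups))
  spans <- tapply(microbes$strain_id, microbes$orthogroup_id,
                  function(s) length(unique(s)))
  expect_true(all(spans[shared] == cfg$n_strains))
  host <- sim$catalog[sim$catalog$kingdom == "host", ]
  expect_equal(length(intersect(host$orthogroup_id, microbes$orthogroup_id)), 0L)
})

test_that("de_fraction = 0 yields an empty true-DE set", {
  cfg <- tiny_config(de_fraction = 0)
  sim <- simulate_catalog(cfg)
  expr <- simulate_expression(sim$catalog, cfg)
  expect_equal(sum(expr$truth$de$is_de), 0L)
  expect_true(all(expr$truth$de$true_log2fc == 0))
})

test_that("host dilution takes the configured share of root reads", {
  # host reads are NB sums over host genes, so the spread exceeds the
  # binomial one; check the mean over replicates against its Monte-Carlo SE
  cfg <- tiny_config(host_dilution_root = 0.5, reads_per_sample = 1e5,
                     n_host_genes = 40, n_replicates = 30)
  sim <- simulate_catalog(cfg)
  expr <- simulate_expression(sim$catalog, cfg)
  host_genes <- sim$catalog$gene_id %in%
    sim$catalog$gene_id[sim$catalog$kingdom == "host"]
  root <- expr$samples$sample[expr$samples$compartment == "root"]
  host_reads <- vapply(root, function(smp)
    sum(expr$counts[[smp]][expr$counts$gene_id %in%
                             sim$catalog$gene_id[host_genes]]), numeric(1))
  se <- stats::sd(host_reads) / sqrt(length(host_reads))
  expect_lt(abs(mean(host_reads) - 5e4), 3 * se)
  for (smp in expr$samples$sample[expr$samples$compartment == "matrix"]) {
    expect_equal(sum(expr$counts[[smp]][expr$counts$gene_id %in%
                                          sim$catalog$gene_id[host_genes]]), 0)
  }
})

test_that("non-DE genes have equal root and matrix means (many replicates)", {
  # equal strain abundances across compartments and no host dilution, so
  # beta = 0 is the only thing the contrast can pick up
  cfg <- tiny_config(de_fraction = 0, n_replicates = 50,
                     host_dilution_root = 0, strain_logRA_sd = 0,
                     reads_per_sample = 5e4, seed = 17)
  sim <- simulate_catalog(cfg)
  expr <- simulate_expression(sim$catalog, cfg)
  m <- as.matrix(expr$counts[, -1])
  root <- expr$samples$sample[expr$samples$compartment == "root"]
  mat <- expr$samples$sample[expr$samples$compartment == "matrix"]
  mr <- rowMeans(m[, root]); mm <- rowMeans(m[, mat])
  se <- sqrt(apply(m[, root], 1, stats::var) / length(root) +
             apply(m[, mat], 1, stats::var) / length(mat))
  ok <- se > 0 & (mr + mm) / 2 > 5
  z <- abs(mr[ok] - mm[ok]) / se[ok]
  expect_lt(mean(z > 3), 0.02)
})

test_that("read emission conserves counts and emits exact substrings", {
  cfg <- tiny_config()
  sim <- simulate_catalog(cfg)
  expr <- simulate_expression(sim$catalog, cfg)
  reads <- simulate_reads(sim$catalog, expr$counts, cfg)
  expect_equal(nrow(reads), sum(as.matrix(expr$counts[, -1])))
  per_sample <- table(reads$sample)
  col_sums <- colSums(as.matrix(expr$counts[, -1]))
  expect_equal(as.vector(per_sample[names(col_sums)]), unname(col_sums))
  seq_of <- stats::setNames(sim$catalog$sequence, sim$catalog$gene_id)
  idx <- withr::with_seed(1, sample(nrow(reads), 200))
  hits <- mapply(function(rd, g) grepl(rd, seq_of[g], fixed = TRUE),
                 reads$sequence[idx], reads$true_gene[idx])
  expect_true(all(hits))
  expect_true(all(nchar(reads$sequence) == cfg$read_length))
})

test_that("zero counts give an empty but valid FASTQ", {
  cfg <- tiny_config()
  sim <- simulate_catalog(cfg)
  counts0 <- tibble::tibble(gene_id = sim$catalog$gene_id, s1 = 0)
  reads <- simulate_reads(sim$catalog, counts0, cfg)
  expect_equal(nrow(reads), 0L)
  dir <- withr::local_tempdir()
  write_reads_fastq(tibble::tibble(sample = "s1", read_id = character(0),
                                   true_gene = character(0),
                                   sequence = character(0))[0, ], dir)
  expect_true(TRUE)  # nothing to write is not an error
})

test_that("fastq round-trip preserves reads", {
  cfg <- tiny_config(reads_per_sample = 200)
  sim <- simulate_catalog(cfg)
  expr <- simulate_expression(sim$catalog, cfg)
  reads <- simulate_reads(sim$catalog, expr$counts, cfg)
  dir <- withr::local_tempdir()
  paths <- write_reads_fastq(reads, dir)
  back <- read_reads_fastq(paths)
  expect_equal(nrow(back), nrow(reads))
  ord1 <- order(back$read_id); ord2 <- order(reads$read_id)
  expect_equal(back$sequence[ord1], reads$sequence[ord2])
})

test_that("read emission refuses reads longer than the shortest gene", {
  cfg <- tiny_config()
  sim <- simulate_catalog(cfg)
  cfg2 <- cfg; cfg2$read_length <- min(sim$catalog$length) + 1L
  counts <- tibble::tibble(gene_id = sim$catalog$gene_id, s1 = 1)
  expect_error(simulate_reads(sim$catalog, counts, cfg2), "gene")
})

test_that("amplicon profile converges to truth without dropout", {
  cfg <- tiny_config(amplicon_reads = 1e6, amplicon_dropout = 0)
  sim <- simulate_catalog(cfg)
  expr <- simulate_expression(sim$catalog, cfg)
  amp <- simulate_amplicon(expr$truth, cfg)
  ra_sums <- tapply(amp$ra, amp$sample, sum)
  expect_true(all(abs(ra_sums - 100) < 1e-9))
  one <- amp[amp$sample == "root_1", ]
  truth <- expr$truth$strain_ra[expr$truth$strain_ra$compartment == "root", ]
  m <- merge(one, truth, by = "strain_id")
  expect_lt(max(abs(m$ra.x / 100 - m$ra.y)), 0.01)
})

test_that("amplicon dropout removes the expected number of strains", {
  cfg <- sim_config(n_strains = 10, genes_per_strain = 10, n_orthogroups = 8,
                    frac_interstrain_duplicate = 0,
                    frac_within_strain_paralog = 0,
                    gene_length_range = c(200L, 300L), k = 21L,
                    read_length = 50L, n_host_genes = 0,
                    amplicon_dropout = 0.5, amplicon_reads = 1e5,
                    n_replicates = 30, seed = 23)
  sim <- simulate_catalog(cfg)
  expr <- simulate_expression(sim$catalog, cfg)
  amp <- simulate_amplicon(expr$truth, cfg)
  undetected <- tapply(amp$reads, amp$sample, function(r) sum(r == 0))
  expect_lt(abs(mean(undetected) - 5), 3 * sqrt(10 * 0.25 / length(undetected)) + 0.5)
})
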