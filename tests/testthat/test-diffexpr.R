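two_sample_meta <- function() {
  tibble::tibble(sample = c("s1", "s2"),
                 compartment = c("root", "matrix"), replicate = c(1, 1))
}

test_that("size factors match the hand median-of-ratios computation", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s1 = c(2, 8), s2 = c(4, 16))
  sf <- size_factors(counts, two_sample_meta(), min_ref_genes = 1)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  expect_equal(exp(mean(log(sf$size_factor))), 1, tolerance = 1e-6)
})

test_that("identical columns give unit size factors; single sample is 1", {
  counts <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                           s1 = c(3, 9, 2, 7, 5), s2 = c(3, 9, 2, 7, 5))
  sf <- size_factors(counts, two_sample_meta(), min_ref_genes = 1)
  expect_equal(sf$size_factor, c(1, 1))
  one <- size_factors(tibble::tibble(gene_id = "g1", s1 = 4),
                      tibble::tibble(sample = "s1", compartment = "root",
                                     replicate = 1))
  expect_equal(one$size_factor, 1)
})

test_that("strains without enough all-sample genes raise the eligibility error", {
  counts <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                           s1 = c(1, 0, 2, 0, 3), s2 = c(0, 1, 5, 1, 0))
  err <- tryCatch(size_factors(counts, two_sample_meta(), min_ref_genes = 10),
                  syncomtx_ineligible = function(e) e)
  expect_s3_class(err, "syncomtx_ineligible")
  expect_match(conditionMessage(err), "need >= 10")
})

test_that("raw dispersion follows the moments formula within conditions", {
  # group values chosen so m = 10, v = 36 by hand -> alpha = 26/100
  samples <- samples_3v3()
  counts <- counts_from_matrix(matrix(rep(c(4, 10, 16), each = 2), nrow = 1,
                                      dimnames = list(NULL, samples$sample)))
  counts[1, -1] <- as.list(c(4, 10, 16, 4, 10, 16))
  sf <- tibble::tibble(sample = samples$sample, size_factor = 1)
  disp <- estimate_dispersions(counts, samples, sf)
  expect_equal(disp$alpha_raw, (36 - 10) / 100, tolerance = 1e-12)
})

test_that("Poisson-like genes end near the dispersion floor", {
  sim <- nb_counts(300, a0 = 1e-9, a1 = 1e-9, seed = 5)
  sf <- size_factors(sim$counts, sim$samples)
  disp <- estimate_dispersions(sim$counts, sim$samples, sf)
  expect_lt(stats::median(disp$alpha, na.rm = TRUE), 0.05)
})

test_that("known dispersion is recovered at many replicates", {
  n_genes <- 400
  sim <- nb_counts(n_genes, n_rep = 50, a0 = 0.1, a1 = 1e-9,
                   mean_log = log(200), mean_sd = 0.5, seed = 6)
  sf <- size_factors(sim$counts, sim$samples)
  disp <- estimate_dispersions(sim$counts, sim$samples, sf)
  expect_gt(stats::median(disp$alpha, na.rm = TRUE), 0.05)
  expect_lt(stats::median(disp$alpha, na.rm = TRUE), 0.2)
})

test_that("Wald test recovers the closed-form fold change", {
  samples <- samples_3v3()
  m <- rbind(c(40, 40, 40, 10, 10, 10),
             c(7, 7, 7, 7, 7, 7))
  colnames(m) <- samples$sample
  counts <- counts_from_matrix(m)
  sf <- tibble::tibble(sample = samples$sample, size_factor = 1)
  disp <- tibble::tibble(feature_id = counts$gene_id,
                         base_mean = rowMeans(m), alpha_raw = 1e-8,
                         alpha_trend = 1e-8, alpha = 1e-8, tested = TRUE)
  de <- nb_wald_test(counts, samples, sf, disp)
  expect_equal(de$log2fc_mle[1], 2, tolerance = 1e-6)
  expect_equal(de$log2fc_mle[2], 0, tolerance = 1e-9)
  expect_gt(de$pvalue[2], 0.999)
})

test_that("the Poisson-limit fold change equals the log mean ratio", {
  sim <- nb_counts(100, a0 = 1e-9, a1 = 1e-9, seed = 7,
                   mean_log = log(500), mean_sd = 0.3)
  samples <- sim$samples
  sf <- tibble::tibble(sample = samples$sample, size_factor = 1)
  m <- as.matrix(sim$counts[, -1])
  disp <- tibble::tibble(feature_id = sim$counts$gene_id,
                         base_mean = rowMeans(m), alpha_raw = 1e-8,
                         alpha_trend = 1e-8, alpha = 1e-8, tested = TRUE)
  de <- nb_wald_test(sim$counts, samples, sf, disp)
  root <- samples$sample[samples$compartment == "root"]
  mat <- samples$sample[samples$compartment == "matrix"]
  expected <- log2(rowMeans(m[, root]) / rowMeans(m[, mat]))
  expect_equal(de$log2fc_mle, expected, tolerance = 1e-3)
})

test_that("all-zero genes are untested and one-sided zeros stay finite", {
  samples <- samples_3v3()
  m <- rbind(c(0, 0, 0, 0, 0, 0), c(50, 60, 55, 0, 0, 0),
             c(20, 22, 18, 21, 20, 19))
  colnames(m) <- samples$sample
  counts <- counts_from_matrix(m)
  fit <- run_de(counts, samples, min_ref_genes = 1)
  expect_false(fit$result$tested[1])
  expect_true(is.na(fit$result$pvalue[1]))
  expect_true(is.finite(fit$result$log2fc_mle[2]))
  expect_true(is.finite(fit$result$se[2]))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  brute_bh <- function(p) {
    n <- sum(!is.na(p))
    ord <- order(p, na.last = NA)
    adj <- rep(NA_real_, length(p))
    ranked <- p[ord] * n / seq_along(ord)
    adj[ord] <- rev(cummin(rev(pmin(ranked, 1))))
    adj
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(9, {
    for (i in 1:20) {
      p <- stats::runif(sample(1:50, 1))
      if (i %% 3 == 0) p[sample(length(p), 1)] <- NA
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("shrinkage has the right limits and never inflates fold changes", {
  de <- tibble::tibble(
    feature_id = sprintf("g%d", 1:4),
    base_mean = c(100, 100, 1, 100),
    log2fc_mle = c(3, 3, 3, 0.2),
    se = c(1e-8, 1e8, 2, 0.01),
    pvalue = c(0.001, 0.9, 0.5, 0.8),
    tested = TRUE
  )
  sh <- shrink_lfc(de)
  expect_equal(sh$log2fc_shrunk[1], 3, tolerance = 1e-6)   # SE -> 0
  expect_lt(abs(sh$log2fc_shrunk[2]), 1e-6)                # SE -> Inf
  expect_true(all(abs(sh$log2fc_shrunk) <= abs(sh$log2fc_mle) + 1e-12))
})

test_that("shrinkage reduces error for low-count genes on simulation", {
  n_genes <- 2000
  beta <- numeric(n_genes)
  withr::with_seed(12, {
    idx <- sample(n_genes, 200)
    beta[idx] <- rep(c(2, -2), 100)
  })
  sim <- nb_counts(n_genes, beta = beta, mean_log = log(20), mean_sd = 2,
                   seed = 13)
  fit <- run_de(sim$counts, sim$samples)
  r <- fit$result
  low <- r$tested & r$base_mean < 10
  rmse <- function(est) sqrt(mean((est[low] - beta[low])^2, na.rm = TRUE))
  expect_lte(rmse(r$log2fc_shrunk), rmse(r$log2fc_mle))
})

test_that("DEG calls are invariant to relabeling samples within a compartment", {
  sim <- nb_counts(300, seed = 14)
  fit1 <- run_de(sim$counts, sim$samples)
  counts2 <- sim$counts[, c("gene_id", "root_2", "root_3", "root_1",
                            "matrix_3", "matrix_1", "matrix_2")]
  names(counts2) <- names(sim$counts)
  # same columns under permuted replicate labels within each compartment
  fit2 <- run_de(counts2, sim$samples)
  expect_equal(sort(fit1$result$feature_id[fit1$result$deg]),
               sort(fit2$result$feature_id[fit2$result$deg]))
  expect_equal(fit1$result$log2fc_mle, fit2$result$log2fc_mle,
               tolerance = 1e-9)
})

test_that("per-strain runs report ineligible strains and housekeeping QC", {
  sim <- nb_counts(100, seed = 15)
  good <- dplyr::mutate(sim$counts, strain_id = "good", .after = 1)
  sparse <- good
  sparse$strain_id <- "sparse"
  sparse$gene_id <- paste0("sp_", sparse$gene_id)
  for (s in sim$samples$sample) {
    sparse[[s]] <- ifelse(seq_len(nrow(sparse)) %% 2 == 0, 0, sparse[[s]])
    sparse[[s]][seq_len(nrow(sparse)) %% 3 == 0] <- 0
  }
  sparse_zeroed <- sparse
  # make fewer than 10 genes detected in all samples
  keep_rows <- seq_len(nrow(sparse)) > 5
  for (s in sim$samples$sample) sparse_zeroed[[s]][keep_rows & (seq_len(nrow(sparse)) %% 2 == 1)] <- 0
  res <- run_per_strain_de(dplyr::bind_rows(good, sparse_zeroed),
                           sim$samples,
                           housekeeping_genes = good$gene_id[1:3])
  expect_true("good" %in% names(res$fits))
  expect_true("sparse" %in% res$ineligible$strain_id)
  expect_match(res$ineligible$reason[1], "detected in all samples")
  expect_s3_class(tidy(res), "tbl_df")
  expect_true(all(c("strain_id", "feature_id") %in% names(tidy(res))))
  expect_equal(nrow(res$housekeeping_qc), 3L)
})

test_that("a missing compartment is an error", {
  sim <- nb_counts(50, seed = 16)
  samples_root <- sim$samples[sim$samples$compartment == "root", ]
  counts <- dplyr::mutate(sim$counts, strain_id = "A", .after = 1)
  expect_error(run_per_strain_de(counts, samples_root), "both compartments")
})

test_that("the DE core agrees with an established NB implementation", {
  skip_if_not_installed("DESeq2")
  sim <- nb_counts(400, beta = c(rep(2, 20), rep(0, 380)), seed = 18)
  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$gene_id
  sf <- size_factors(sim$counts, sim$samples)
  dds_sf <- DESeq2::estimateSizeFactorsForMatrix(m)
  dds_sf <- dds_sf / exp(mean(log(dds_sf)))  # same geometric-mean-1 scale
  expect_equal(sf$size_factor, unname(dds_sf[sf$sample]), tolerance = 1e-6)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      m, data.frame(condition = factor(sim$samples$compartment,
                                       levels = c("matrix", "root"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  fit <- run_de(sim$counts, sim$samples)
  ok <- fit$result$tested & !is.na(res$log2FoldChange)
  # rank agreement over all genes (genes with one all-zero group get an
  # unmoderated extreme MLE here vs a moderated one there), near-identity
  # away from the zero boundary
  expect_gt(stats::cor(fit$result$log2fc_mle[ok], res$log2FoldChange[ok],
                       method = "spearman"), 0.99)
  ok2 <- ok & fit$result$base_mean > 10
  expect_gt(stats::cor(fit$result$log2fc_mle[ok2], res$log2FoldChange[ok2]),
            0.99)
  expect_gt(stats::cor(fit$result$pvalue[ok2], res$pvalue[ok2],
                       method = "spearman"), 0.99)
})
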