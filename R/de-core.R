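ALPHA_MIN <- 1e-8
ETA_MIN <- log(1e-8)

as_count_matrix <- function(counts, samples) {
  id_col <- if ("feature_id" %in% names(counts)) "feature_id" else "gene_id"
  smp <- intersect(names(counts), samples$sample)
  if (length(smp) < nrow(samples)) {
    stop("count table is missing sample column(s): ",
         paste(setdiff(samples$sample, smp), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(counts[, samples$sample, drop = FALSE])
  rownames(m) <- counts[[id_col]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  m
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed from genes detected in all
#' samples (the reference set): \eqn{s_j = median_i\, k_{ij} / g_i} with
#' \eqn{g_i} the geometric mean of gene i across samples, rescaled so the
#' size factors have geometric mean 1.
#'
#' @param counts Wide count tibble (`gene_id`/`feature_id` + sample columns).
#' @param samples Sample metadata tibble (`sample`, `compartment`).
#' @param min_ref_genes Minimum number of all-sample-detected reference genes;
#'   below this the strain is not normalizable and a classed error
#'   (`syncomtx_ineligible`) is raised.
#' @return Tibble: `sample`, `size_factor`.
#' @export
size_factors <- function(counts, samples, min_ref_genes = 10) {
  m <- as_count_matrix(counts, samples)
  if (ncol(m) == 1L) {
    return(tibble::tibble(sample = colnames(m), size_factor = 1))
  }
  ref <- rowSums(m > 0) == ncol(m)
  if (sum(ref) < max(min_ref_genes, 1)) {
    stop(structure(class = c("syncomtx_ineligible", "error", "condition"),
                   list(message = paste0("only ", sum(ref), " gene(s) detected in all samples (need >= ",
                                         min_ref_genes, ")"),
                        call = NULL)))
  }
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  s <- apply(exp(logm - loggeo), 2, stats::median)
  s <- s / exp(mean(log(s)))
  tibble::tibble(sample = colnames(m), size_factor = unname(s))
}

#' Per-gene NB dispersion estimates with trend shrinkage
#'
#' Raw dispersions come from within-condition method of moments on normalized
#' counts, \eqn{\hat\alpha = max(\alpha_{min}, (\hat v - \hat m)/\hat m^2)}
#' pooled across conditions with df weights; a mean-dispersion trend
#' \eqn{\alpha(m) = a_0 + a_1/m} is fitted by least squares over genes with
#' above-floor raw estimates, and the final dispersion is the geometric mean
#' of the raw and trend values (a simple shrinkage toward the trend that
#' stabilizes the few-replicate estimates).
#'
#' @param counts,samples As in [size_factors()].
#' @param sf Size-factor tibble from [size_factors()].
#' @return Tibble: `feature_id`, `base_mean`, `alpha_raw`, `alpha_trend`,
#'   `alpha`, `tested` (FALSE for all-zero genes).
#' @export
estimate_dispersions <- function(counts, samples, sf) {
  m <- as_count_matrix(counts, samples)
  s <- sf$size_factor[match(colnames(m), sf$sample)]
  z <- sweep(m, 2, s, "/")
  cond <- samples$compartment[match(colnames(m), samples$sample)]
  groups <- unique(cond)

  num <- matrix(0, nrow(m), length(groups))
  den <- matrix(0, nrow(m), length(groups))
  for (gi in seq_along(groups)) {
    cols <- cond == groups[gi]
    n_c <- sum(cols)
    if (n_c < 2L) next
    zc <- z[, cols, drop = FALSE]
    mc <- rowMeans(zc)
    vc <- rowSums((zc - mc)^2) / (n_c - 1)
    ok <- mc > 0
    num[ok, gi] <- (n_c - 1) * (vc[ok] - mc[ok]) / mc[ok]^2
    den[ok, gi] <- (n_c - 1)
  }
  df <- rowSums(den)
  alpha_raw <- ifelse(df > 0, rowSums(num) / pmax(df, 1), NA_real_)
  alpha_raw <- pmax(alpha_raw, ALPHA_MIN)

  base_mean <- rowMeans(z)
  tested <- base_mean > 0
  alpha_raw[!tested] <- NA_real_

  fit_set <- which(tested & !is.na(alpha_raw) & alpha_raw > ALPHA_MIN)
  alpha_trend <- rep(NA_real_, nrow(m))
  if (length(fit_set) >= 3L) {
    x <- 1 / base_mean[fit_set]
    fit <- stats::lm.fit(cbind(1, x), alpha_raw[fit_set])
    a <- fit$coefficients
    alpha_trend[tested] <- pmax(a[1] + a[2] / base_mean[tested], ALPHA_MIN)
  } else {
    alpha_trend[tested] <- mean(alpha_raw[tested], na.rm = TRUE)
  }
  # weighted geometric mean: the raw moments estimate has only a couple of
  # residual df per condition and is much noisier than the fitted trend, so
  # the trend gets double weight; a raw estimate at the floor (the moments
  # difference was <= 0) carries no dispersion information and those genes
  # take the trend value outright
  w_raw <- 1 / 3
  alpha <- ifelse(alpha_raw > ALPHA_MIN,
                  alpha_raw^w_raw * alpha_trend^(1 - w_raw),
                  alpha_trend)

  tibble::tibble(feature_id = rownames(m), base_mean = base_mean,
                 alpha_raw = alpha_raw, alpha_trend = alpha_trend,
                 alpha = alpha, tested = tested)
}

# groupwise NB log-mean fit by Fisher scoring; returns eta, observed info,
# convergence flag (matrices/vectors over genes)
nb_group_fit <- function(y, s, alpha, max_iter = 100L, tol = 1e-8) {
  eta <- log(pmax(rowMeans(sweep(y, 2, s, "/")), 1e-8))
  converged <- rep(FALSE, nrow(y))
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% s
    w <- 1 + alpha * mu
    U <- rowSums((y - mu) / w)
    J <- rowSums(mu / w)
    step <- U / pmax(J, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    eta_new <- pmin(pmax(eta + step, ETA_MIN), log(1e12))
    moved <- abs(eta_new - eta)
    eta <- eta_new
    converged <- converged | moved < tol | (eta <= ETA_MIN & U < 0)
    if (all(converged)) break
  }
  mu <- exp(eta) %o% s
  r <- 1 / alpha
  info_obs <- rowSums(mu * (y + r) * r / (mu + r)^2)
  list(eta = eta, info = info_obs, converged = converged)
}

#' Per-gene NB Wald test of root vs matrix differential expression
#'
#' Fits, gene by gene, the NB GLM
#' \eqn{\log \mu_{ij} = \log s_j + \beta_0 + \beta_1 x_j} (x = 1 for root,
#' 0 for matrix) with fixed gene dispersion, by Fisher-scoring IRLS;
#' `log2fc_mle` is \eqn{\beta_1/\ln 2}, its standard error comes from the
#' observed information, and the Wald p-value is
#' \eqn{2(1 - \Phi(|\beta_1|/SE))}. Positive log2FC means higher expression
#' in roots.
#'
#' @param counts,samples As in [size_factors()].
#' @param sf Size factors tibble.
#' @param disp Dispersion tibble from [estimate_dispersions()].
#' @return Tibble: `feature_id`, `base_mean`, `log2fc_mle`, `se`, `pvalue`,
#'   `tested`. Untested (all-zero or non-converged) features carry NA stats.
#' @export
nb_wald_test <- function(counts, samples, sf, disp) {
  m <- as_count_matrix(counts, samples)
  s <- sf$size_factor[match(colnames(m), sf$sample)]
  cond <- samples$compartment[match(colnames(m), samples$sample)]
  if (!all(c("root", "matrix") %in% cond)) {
    stop("both compartments must be present", call. = FALSE)
  }
  alpha <- disp$alpha[match(rownames(m), disp$feature_id)]
  tested <- disp$tested[match(rownames(m), disp$feature_id)]
  alpha[is.na(alpha)] <- ALPHA_MIN

  root_cols <- cond == "root"
  fit_r <- nb_group_fit(m[, root_cols, drop = FALSE], s[root_cols], alpha)
  fit_m <- nb_group_fit(m[, !root_cols, drop = FALSE], s[!root_cols], alpha)

  conv <- fit_r$converged & fit_m$converged
  if (any(tested & !conv)) {
    warning(sum(tested & !conv), " feature(s) did not converge; marked untested",
            call. = FALSE)
  }
  tested <- tested & conv

  b <- fit_r$eta - fit_m$eta
  se_nat <- sqrt(1 / pmax(fit_r$info, 1e-300) + 1 / pmax(fit_m$info, 1e-300))
  log2fc <- b / log(2)
  se <- se_nat / log(2)
  p <- 2 * stats::pnorm(abs(b) / se_nat, lower.tail = FALSE)

  out <- tibble::tibble(
    feature_id = rownames(m),
    base_mean = unname(disp$base_mean[match(rownames(m), disp$feature_id)]),
    log2fc_mle = unname(log2fc), se = unname(se), pvalue = unname(p),
    tested = unname(tested)
  )
  out$log2fc_mle[!tested] <- NA_real_
  out$se[!tested] <- NA_real_
  out$pvalue[!tested] <- NA_real_
  out
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Normal-prior shrinkage so fold changes of low-count features are not
#' over-estimated: the prior SD \eqn{\tau} is the upper quartile of
#' \eqn{|log2FC_{mle}|} over well-estimated features (SE below the median
#' SE), and \eqn{log2FC_{shrunk} = log2FC_{mle}\,\tau^2/(\tau^2 + SE^2)}.
#'
#' @param de Tibble from [nb_wald_test()].
#' @return The input with a `log2fc_shrunk` column added
#'   (`|shrunk| <= |mle|`; features with infinite or missing SE shrink to 0
#'   when any usable prior exists, and the shrunk value is 0 throughout in
#'   the degenerate all-SE-infinite case).
#' @export
shrink_lfc <- function(de) {
  stopifnot(all(c("log2fc_mle", "se") %in% names(de)))
  ok <- de$tested & is.finite(de$se) & is.finite(de$log2fc_mle)
  if (!any(ok)) {
    de$log2fc_shrunk <- ifelse(de$tested, 0, NA_real_)
    return(de)
  }
  med_se <- stats::median(de$se[ok])
  prior_set <- ok & de$se < med_se
  if (!any(prior_set)) prior_set <- ok
  tau <- stats::quantile(abs(de$log2fc_mle[prior_set]), 0.75, names = FALSE)
  if (!is.finite(tau) || tau <= 0) tau <- 1e-6
  shrunk <- de$log2fc_mle * tau^2 / (tau^2 + de$se^2)
  shrunk[de$tested & !is.finite(shrunk)] <- 0
  shrunk[!de$tested] <- NA_real_
  de$log2fc_shrunk <- shrunk
  de
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH over the non-missing p-values (NAs are passed through and do
#' not count toward the number of tests).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH", n = sum(!is.na(pvals)))
}

#' Full NB differential-expression run on one count table
#'
#' Chains [size_factors()], [estimate_dispersions()], [nb_wald_test()],
#' [shrink_lfc()] and [bh_adjust()]; the root-vs-matrix contrast is taken
#' from the `compartment` column of `samples`.
#'
#' @param counts Wide count tibble (`gene_id`/`feature_id` + sample columns).
#' @param samples Sample metadata (`sample`, `compartment`).
#' @param min_ref_genes Eligibility threshold passed to [size_factors()].
#' @param alpha_sig Significance level on adjusted p for the `deg` call.
#' @return Object of class `syncom_de` with elements `result` (tibble:
#'   `feature_id`, `base_mean`, `log2fc_mle`, `se`, `log2fc_shrunk`,
#'   `pvalue`, `padj`, `tested`, `deg`), `size_factors`, `dispersions`,
#'   `alpha_sig`.
#' @export
run_de <- function(counts, samples, min_ref_genes = 10, alpha_sig = 0.05) {
  sf <- size_factors(counts, samples, min_ref_genes = min_ref_genes)
  disp <- estimate_dispersions(counts, samples, sf)
  de <- nb_wald_test(counts, samples, sf, disp)
  de <- shrink_lfc(de)
  de$padj <- bh_adjust(de$pvalue)
  de$deg <- !is.na(de$padj) & de$padj < alpha_sig
  structure(list(result = de, size_factors = sf, dispersions = disp,
                 alpha_sig = alpha_sig),
            class = "syncom_de")
}

#' @export
print.syncom_de <- function(x, ...) {
  cat("<syncom_de> ", nrow(x$result), " features; ", sum(x$result$tested),
      " tested; ", sum(x$result$deg), " DE at padj < ", x$alpha_sig, "\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_de
#' @param x A `syncom_de` object.
#' @param ... Unused.
#' @export
tidy.syncom_de <- function(x, ...) x$result

#' @rdname run_de
#' @export
glance.syncom_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$result),
    n_tested = sum(x$result$tested),
    n_deg = sum(x$result$deg),
    n_up = sum(x$result$deg & x$result$log2fc_shrunk > 0, na.rm = TRUE),
    n_down = sum(x$result$deg & x$result$log2fc_shrunk < 0, na.rm = TRUE),
    alpha_sig = x$alpha_sig
  )
}
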