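#' Simulate negative-binomial expression counts for a SynCom catalog
#'
#' Generates a gene-by-sample count table contrasting root and matrix
#' compartments. Per-strain relative abundances are log-normal and drawn
#' independently per compartment (strains colonize root and matrix
#' differently); within a strain, gene expression shares follow a log-normal
#' profile. For gene g in sample j the count is drawn from
#' \deqn{k_{gj} \sim NB(\mu_{gj},\ \alpha_g),\qquad
#'   \mu_{gj} = L_j\, RA_{s(g),c(j)}\, q_g\, 2^{x_j \beta_g},}
#' with \eqn{x_j = 1} for root samples, \eqn{\beta_g = \pm}`de_log2fc` for
#' true-DE genes (half up, half down in roots) and 0 otherwise, and the
#' dispersion trend \eqn{\alpha_g = a_0 + a_1/\mu}. Root samples lose
#' `host_dilution_root` of their read budget to host genes, which are
#' simulated from the same NB model on the host side.
#'
#' Conserved root responses are planted at orthogroup level: each of
#' `n_conserved_ogs` shared orthogroups gets \eqn{\beta = +}`de_log2fc` for
#' its member genes in a fixed majority subset of strains.
#'
#' @param catalog Catalog tibble from [simulate_catalog()].
#' @param config The same [sim_config()] used to build the catalog.
#' @return A list with `counts` (tibble, `gene_id` + one column per sample),
#'   `samples` (tibble: `sample`, `compartment`, `replicate`) and `truth`
#'   (list: `strain_ra` with per-compartment fractions summing to 1 over
#'   microbial strains, `de` with per-gene true log2FC, `conserved_ogs`,
#'   and `conserved_responses` mapping planted orthogroup-strain pairs).
#' @export
simulate_expression <- function(catalog, config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed + 1L)

  microbes <- catalog[catalog$kingdom != "host", ]
  strains <- unique(microbes$strain_id)
  n_rep <- cfg$n_replicates
  samples <- tibble::tibble(
    sample = c(sprintf("root_%d", seq_len(n_rep)), sprintf("matrix_%d", seq_len(n_rep))),
    compartment = rep(c("root", "matrix"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2L)
  )

  # per-compartment log-normal strain abundances
  ra <- lapply(stats::setNames(nm = c("root", "matrix")), function(cmp) {
    w <- exp(stats::rnorm(length(strains), 0, cfg$strain_logRA_sd))
    stats::setNames(w / sum(w), strains)
  })
  strain_ra <- dplyr::bind_rows(lapply(names(ra), function(cmp)
    tibble::tibble(strain_id = strains, compartment = cmp, ra = unname(ra[[cmp]]))))

  # within-strain expression shares
  q <- exp(stats::rnorm(nrow(microbes), 0, 1))
  q <- unlist(lapply(split(q, microbes$strain_id)[strains], function(v) v / sum(v)),
              use.names = FALSE)
  # split() orders groups by factor level; restore catalog row order
  ord <- order(match(microbes$strain_id, strains))
  qq <- numeric(nrow(microbes)); qq[ord] <- q
  microbes$q <- qq

  # true effects: planted conserved orthogroup responses first, then random DE
  beta <- numeric(nrow(microbes))
  conserved_ogs <- character(0)
  conserved_resp <- tibble::tibble(orthogroup_id = character(0), strain_id = character(0))
  if (cfg$n_conserved_ogs > 0L) {
    shared <- sprintf("OG%05d", seq_len(cfg$n_orthogroups))
    conserved_ogs <- sample(shared, cfg$n_conserved_ogs)
    n_resp <- ceiling(cfg$conserved_strain_frac * length(strains))
    for (og in conserved_ogs) {
      resp <- sample(strains, n_resp)
      hit <- microbes$orthogroup_id == og & microbes$strain_id %in% resp
      beta[hit] <- cfg$de_log2fc
      conserved_resp <- dplyr::bind_rows(conserved_resp,
        tibble::tibble(orthogroup_id = og, strain_id = resp))
    }
  }
  free <- which(beta == 0 & !(microbes$orthogroup_id %in% conserved_ogs))
  n_de <- round(cfg$de_fraction * nrow(microbes))
  n_de <- min(n_de, length(free))
  if (n_de > 0L) {
    idx <- sample(free, n_de)
    sgn <- rep(c(1, -1), length.out = n_de)
    beta[idx] <- sgn * cfg$de_log2fc
  }
  microbes$beta <- beta

  counts <- matrix(0, nrow(microbes), nrow(samples),
                   dimnames = list(microbes$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    cmp <- samples$compartment[j]
    dil <- if (cmp == "root") cfg$host_dilution_root else 0
    budget <- cfg$reads_per_sample * (1 - dil)
    x <- as.integer(cmp == "root")
    mu <- budget * ra[[cmp]][microbes$strain_id] * microbes$q * 2^(x * microbes$beta)
    alpha <- cfg$dispersion_a0 + cfg$dispersion_a1 / pmax(mu, 1e-8)
    counts[, j] <- stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  }

  host <- catalog[catalog$kingdom == "host", ]
  if (nrow(host) > 0L) {
    qh <- exp(stats::rnorm(nrow(host), 0, 1)); qh <- qh / sum(qh)
    hcounts <- matrix(0, nrow(host), nrow(samples),
                      dimnames = list(host$gene_id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      dil <- if (samples$compartment[j] == "root") cfg$host_dilution_root else 0
      if (dil > 0) {
        mu <- cfg$reads_per_sample * dil * qh
        alpha <- cfg$dispersion_a0 + cfg$dispersion_a1 / pmax(mu, 1e-8)
        hcounts[, j] <- stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
      }
    }
    counts <- rbind(counts, hcounts)
  }

  de <- tibble::tibble(gene_id = microbes$gene_id,
                       true_log2fc = microbes$beta,
                       is_de = microbes$beta != 0)

  list(
    counts = tibble::as_tibble(cbind(tibble::tibble(gene_id = rownames(counts)),
                                     as.data.frame(counts))),
    samples = samples,
    truth = list(strain_ra = strain_ra, de = de,
                 conserved_ogs = conserved_ogs,
                 conserved_responses = conserved_resp)
  )
}
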