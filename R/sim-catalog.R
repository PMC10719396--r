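#' @importFrom rlang .data
#' @import tibble
NULL

COG_CATEGORIES <- c("C", "E", "G", "J", "K", "L", "M", "O", "P", "T")

random_dna <- function(lengths) {
  if (length(lengths) == 0L) return(character(0))
  total <- sum(lengths)
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  f <- rep.int(seq_along(lengths), lengths)
  out <- vapply(split(bases, f), paste0, character(1), collapse = "")
  unname(out)
}

#' Simulate a multi-strain SynCom gene catalog
#'
#' Builds a coding-sequence catalog for a synthetic community: `n_orthogroups`
#' shared orthogroups with one member gene per strain, strain-specific
#' singleton orthogroups for the remaining genes, exact interstrain sequence
#' duplicates (identical genes carried by two strains), within-strain
#' identical paralog pairs, and a block of host genes that share no
#' orthogroups with the microbes. Multi-genome reference catalogs genuinely
#' contain such identical genes, which is why downstream read assignment must
#' be duplicate-aware.
#'
#' @param config A [sim_config()].
#' @return A list with elements `catalog` (tibble: `gene_id`, `strain_id`,
#'   `kingdom`, `sequence`, `length`, `orthogroup_id`, `cog_category`,
#'   `go_terms`) and `truth` (list carrying `identity`, a tibble mapping each
#'   duplicated gene to its constructed identity group).
#' @export
#' @examples
#' sim <- simulate_catalog(sim_config(n_strains = 2, genes_per_strain = 10,
#'                                    n_orthogroups = 8, seed = 42))
#' sim$catalog
simulate_catalog <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  strains <- c(
    if (cfg$n_strains > cfg$n_fungal_strains)
      sprintf("B%02d", seq_len(cfg$n_strains - cfg$n_fungal_strains)),
    if (cfg$n_fungal_strains > 0L)
      sprintf("F%02d", seq_len(cfg$n_fungal_strains))
  )
  kingdoms <- c(rep("bacteria", cfg$n_strains - cfg$n_fungal_strains),
                rep("fungi", cfg$n_fungal_strains))

  g <- cfg$genes_per_strain
  m <- cfg$n_orthogroups
  n_singleton <- g - m

  gene_id <- as.vector(vapply(strains, function(s) sprintf("%s_g%04d", s, seq_len(g)),
                              character(g)))
  strain_id <- rep(strains, each = g)
  kingdom <- rep(kingdoms, each = g)

  # gene j <= m of every strain belongs to shared OG j; the rest are singletons
  shared_og <- sprintf("OG%05d", seq_len(m))
  og_per_strain <- function(s_idx) {
    c(shared_og,
      if (n_singleton > 0L)
        sprintf("OG%05d", m + (s_idx - 1L) * n_singleton + seq_len(n_singleton)))
  }
  orthogroup_id <- as.vector(vapply(seq_along(strains), og_per_strain, character(g)))

  lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 length(gene_id), replace = TRUE)
  seqs <- random_dna(lens)

  catalog <- tibble::tibble(
    gene_id = gene_id, strain_id = strain_id, kingdom = kingdom,
    sequence = seqs, length = lens, orthogroup_id = orthogroup_id
  )

  identity_rows <- list()

  # interstrain duplication events: copy one gene's sequence across a random
  # pair of strains inside one shared OG; an OG can host several events as
  # long as each member gene is used at most once, so every duplicated gene
  # ends up in exactly one cross-strain identity class
  n_dup_events <- round(cfg$frac_interstrain_duplicate * g * cfg$n_strains / 2)
  if (n_dup_events > 0L) {
    avail <- replicate(m, seq_len(cfg$n_strains), simplify = FALSE)
    for (e in seq_len(n_dup_events)) {
      open <- which(lengths(avail) >= 2L)
      og <- open[sample.int(length(open), 1L)]
      pair <- sample(avail[[og]], 2L)
      avail[[og]] <- setdiff(avail[[og]], pair)
      i1 <- (pair[1] - 1L) * g + og
      i2 <- (pair[2] - 1L) * g + og
      catalog$sequence[i2] <- catalog$sequence[i1]
      catalog$length[i2] <- catalog$length[i1]
      identity_rows[[length(identity_rows) + 1L]] <- tibble::tibble(
        gene_id = catalog$gene_id[c(i1, i2)],
        identity_group = sprintf("dup_is_%03d", e),
        scope = "interstrain_duplicate"
      )
    }
  }

  # within-strain paralog pairs drawn from strain-specific singleton genes
  n_par_events <- round(cfg$frac_within_strain_paralog * g * cfg$n_strains / 2)
  if (n_par_events > 0L) {
    capacity <- floor(n_singleton / 2)
    strain_slots <- rep(seq_len(cfg$n_strains), each = capacity)
    slots <- sample(strain_slots, n_par_events)
    used <- vector("list", cfg$n_strains)
    for (e in seq_len(n_par_events)) {
      s <- slots[e]
      avail <- setdiff(seq_len(n_singleton), used[[s]])
      pick <- sample(avail, 2L)
      used[[s]] <- c(used[[s]], pick)
      i1 <- (s - 1L) * g + m + pick[1]
      i2 <- (s - 1L) * g + m + pick[2]
      catalog$sequence[i2] <- catalog$sequence[i1]
      catalog$length[i2] <- catalog$length[i1]
      catalog$orthogroup_id[i2] <- catalog$orthogroup_id[i1]
      identity_rows[[length(identity_rows) + 1L]] <- tibble::tibble(
        gene_id = catalog$gene_id[c(i1, i2)],
        identity_group = sprintf("dup_ws_%03d", e),
        scope = "within_strain_paralog"
      )
    }
  }

  # functional labels are attached per orthogroup so that members agree
  ogs <- unique(catalog$orthogroup_id)
  og_cog <- sample(c(COG_CATEGORIES, NA), length(ogs), replace = TRUE,
                   prob = c(rep(0.9 / length(COG_CATEGORIES), length(COG_CATEGORIES)), 0.1))
  names(og_cog) <- ogs
  go_pool <- lapply(stats::setNames(nm = COG_CATEGORIES), function(cc)
    sprintf("GO:%07d", which(COG_CATEGORIES == cc) * 100 + 1:5))
  catalog$cog_category <- unname(og_cog[catalog$orthogroup_id])
  catalog$go_terms <- vapply(catalog$cog_category, function(cc) {
    if (is.na(cc)) return("")
    paste(sample(go_pool[[cc]], sample(1:3, 1)), collapse = ";")
  }, character(1))
  catalog$cog_category[is.na(catalog$cog_category)] <- "unknown"

  # host gene block: own kingdom, no orthogroup sharing with microbes
  if (cfg$n_host_genes > 0L) {
    h_lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                     cfg$n_host_genes, replace = TRUE)
    host <- tibble::tibble(
      gene_id = sprintf("host_g%04d", seq_len(cfg$n_host_genes)),
      strain_id = "host", kingdom = "host",
      sequence = random_dna(h_lens), length = h_lens,
      orthogroup_id = sprintf("OGH%05d", seq_len(cfg$n_host_genes)),
      cog_category = "unknown", go_terms = ""
    )
    catalog <- dplyr::bind_rows(catalog, host)
  }

  identity <- if (length(identity_rows)) dplyr::bind_rows(identity_rows) else
    tibble::tibble(gene_id = character(0), identity_group = character(0),
                   scope = character(0))

  list(catalog = catalog, truth = list(identity = identity))
}
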