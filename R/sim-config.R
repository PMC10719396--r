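#' Simulation configuration for a synthetic SynCom experiment
#'
#' Bundles every knob of the synthetic-community generator: community
#' composition, gene-catalog structure (shared orthogroups, exact interstrain
#' duplicates, within-strain identical paralogs), the negative-binomial
#' expression model contrasting root and matrix compartments, read emission,
#' and host-read dilution of root samples.
#'
#' The defaults emulate the design of a gnotobiotic root-colonization
#' experiment: three replicates per compartment, roughly half of the reads in
#' root samples coming from the host, a log-normal spread of strain abundances
#' that differs between compartments, and a dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}.
#'
#' @param n_strains Number of microbial strains.
#' @param n_fungal_strains How many of the strains are fungi (the rest are
#'   bacteria). Community-scale orthogroup analyses use bacteria only.
#' @param genes_per_strain Genes in each strain's coding-sequence catalog.
#' @param n_orthogroups Number of multi-strain (shared) orthogroups; each has
#'   one member gene per strain. Must be <= `genes_per_strain`; remaining
#'   genes receive strain-specific singleton orthogroups.
#' @param frac_interstrain_duplicate Fraction of microbial genes belonging to
#'   cross-strain identity classes (byte-identical sequences in >= 2 strains).
#' @param frac_within_strain_paralog Fraction of microbial genes belonging to
#'   within-strain identical-paralog pairs.
#' @param gene_length_range Integer length-2 vector, min/max gene length (bp).
#' @param k K-mer size used downstream; validated against gene lengths.
#' @param read_length Length (bp) of simulated error-free reads.
#' @param n_replicates Replicates per compartment (root and matrix).
#' @param reads_per_sample Total reads emitted per sample.
#' @param host_dilution_root Fraction of each root sample's reads that are
#'   host-derived (matrix samples carry no host reads).
#' @param n_host_genes Number of host genes in the catalog.
#' @param de_fraction Fraction of microbial genes truly differentially
#'   expressed between root and matrix.
#' @param de_log2fc Absolute effect size (log2 units) of true-DE genes; half
#'   are up, half down in roots.
#' @param dispersion_a0,dispersion_a1 Coefficients of the NB dispersion trend
#'   alpha(mu) = a0 + a1/mu.
#' @param strain_logRA_sd SD of per-strain log relative abundance (natural
#'   log), drawn independently per compartment.
#' @param n_conserved_ogs Number of orthogroups planted as conserved root
#'   responses: their member genes get +`de_log2fc` in a fixed majority subset
#'   of strains.
#' @param conserved_strain_frac Fraction of strains (ceiling) in which a
#'   conserved orthogroup responds.
#' @param amplicon_reads Reads per sample for the DNA-based amplicon profile.
#' @param amplicon_dropout Per-strain per-sample detection dropout probability
#'   of the amplicon assay.
#' @param seed Integer RNG seed; fixes all generator output exactly.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 3, genes_per_strain = 20, n_orthogroups = 10,
#'                   reads_per_sample = 500, seed = 1)
sim_config <- function(n_strains = 20,
                       n_fungal_strains = 0,
                       genes_per_strain = 100,
                       n_orthogroups = 80,
                       frac_interstrain_duplicate = 0.1,
                       frac_within_strain_paralog = 0.05,
                       gene_length_range = c(300L, 1500L),
                       k = 31L,
                       read_length = 60L,
                       n_replicates = 3L,
                       reads_per_sample = 1e5,
                       host_dilution_root = 0.51,
                       n_host_genes = 50L,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       dispersion_a0 = 0.05,
                       dispersion_a1 = 1,
                       strain_logRA_sd = 1,
                       n_conserved_ogs = 0L,
                       conserved_strain_frac = 0.75,
                       amplicon_reads = 1e4,
                       amplicon_dropout = 0,
                       seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    n_fungal_strains = as.integer(n_fungal_strains),
    genes_per_strain = as.integer(genes_per_strain),
    n_orthogroups = as.integer(n_orthogroups),
    frac_interstrain_duplicate = frac_interstrain_duplicate,
    frac_within_strain_paralog = frac_within_strain_paralog,
    gene_length_range = as.integer(gene_length_range),
    k = as.integer(k),
    read_length = as.integer(read_length),
    n_replicates = as.integer(n_replicates),
    reads_per_sample = as.numeric(reads_per_sample),
    host_dilution_root = host_dilution_root,
    n_host_genes = as.integer(n_host_genes),
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    dispersion_a0 = dispersion_a0,
    dispersion_a1 = dispersion_a1,
    strain_logRA_sd = strain_logRA_sd,
    n_conserved_ogs = as.integer(n_conserved_ogs),
    conserved_strain_frac = conserved_strain_frac,
    amplicon_reads = as.numeric(amplicon_reads),
    amplicon_dropout = amplicon_dropout,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  frac_fields <- c("frac_interstrain_duplicate", "frac_within_strain_paralog",
                   "host_dilution_root", "de_fraction", "conserved_strain_frac",
                   "amplicon_dropout")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("`", f, "` must be a single fraction in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_strains < 1L) stop("need at least one strain", call. = FALSE)
  if (cfg$n_fungal_strains < 0L || cfg$n_fungal_strains > cfg$n_strains) {
    stop("`n_fungal_strains` must be between 0 and `n_strains`", call. = FALSE)
  }
  if (cfg$genes_per_strain < 1L) stop("`genes_per_strain` must be >= 1", call. = FALSE)
  if (length(cfg$gene_length_range) != 2L ||
      any(cfg$gene_length_range <= 0L) ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2]) {
    stop("`gene_length_range` must be an increasing pair of positive lengths",
         call. = FALSE)
  }
  if (cfg$k >= cfg$gene_length_range[1]) {
    stop("k-mer size `k` must be smaller than the minimum gene length",
         call. = FALSE)
  }
  if (cfg$read_length > cfg$gene_length_range[1]) {
    stop("`read_length` exceeds the minimum gene length", call. = FALSE)
  }
  if (cfg$read_length < cfg$k) {
    stop("`read_length` must be at least `k`", call. = FALSE)
  }
  if (cfg$reads_per_sample <= 0) stop("`reads_per_sample` must be > 0", call. = FALSE)
  if (cfg$n_replicates < 1L) stop("need at least one replicate per compartment", call. = FALSE)
  if (cfg$n_orthogroups > cfg$genes_per_strain) {
    stop("`n_orthogroups` (shared orthogroups) cannot exceed `genes_per_strain`",
         call. = FALSE)
  }
  if (cfg$frac_interstrain_duplicate > 0 && cfg$n_strains < 2L) {
    stop("interstrain duplicates require at least two strains", call. = FALSE)
  }
  n_dup_events <- round(cfg$frac_interstrain_duplicate *
                          cfg$genes_per_strain * cfg$n_strains / 2)
  dup_capacity <- cfg$n_orthogroups * floor(cfg$n_strains / 2)
  if (n_dup_events > dup_capacity) {
    stop("not enough shared orthogroup members to place ", n_dup_events,
         " interstrain duplication events (capacity ", dup_capacity, ")",
         call. = FALSE)
  }
  n_singletons <- cfg$genes_per_strain - cfg$n_orthogroups
  n_par_events <- round(cfg$frac_within_strain_paralog *
                          cfg$genes_per_strain * cfg$n_strains / 2)
  if (n_par_events > cfg$n_strains * floor(n_singletons / 2)) {
    stop("not enough strain-specific genes to place ", n_par_events,
         " within-strain paralog pairs", call. = FALSE)
  }
  if (cfg$n_conserved_ogs > cfg$n_orthogroups) {
    stop("`n_conserved_ogs` cannot exceed `n_orthogroups`", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_strains, " strains (", x$n_fungal_strains,
      " fungal) x ", x$genes_per_strain, " genes; ",
      x$n_orthogroups, " shared OGs; ",
      x$n_replicates, "+", x$n_replicates, " replicates; ",
      format(x$reads_per_sample, big.mark = ","), " reads/sample; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
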