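#' Compare RNA- and DNA-based strain detection
#'
#' Set algebra per compartment over detection flags from the two profiling
#' methods (a strain counts as detected whenever at least one read was seen
#' in one sample of the compartment).
#'
#' @param rna_flags,dna_flags Detection tibbles (`strain_id`, `compartment`,
#'   `detected`) over the same strain universe, e.g. from [detect_strains()].
#' @param inoculum_size Number of strains in the inoculum, for the reported
#'   fractions (default: size of the shared universe).
#' @return Tibble per compartment: `n_rna`, `n_dna`, `n_both`, `frac_rna`,
#'   `frac_dna`, `frac_both`, and list-columns with the id sets.
#' @export
compare_detection <- function(rna_flags, dna_flags, inoculum_size = NULL) {
  u_rna <- sort(unique(rna_flags$strain_id))
  u_dna <- sort(unique(dna_flags$strain_id))
  if (!identical(u_rna, u_dna)) {
    stop("RNA and DNA profiles cover different strain universes", call. = FALSE)
  }
  if (is.null(inoculum_size)) inoculum_size <- length(u_rna)
  cmp_levels <- union(unique(rna_flags$compartment), unique(dna_flags$compartment))
  out <- lapply(cmp_levels, function(cmp) {
    rna <- rna_flags$strain_id[rna_flags$compartment == cmp & rna_flags$detected]
    dna <- dna_flags$strain_id[dna_flags$compartment == cmp & dna_flags$detected]
    both <- intersect(rna, dna)
    tibble::tibble(
      compartment = cmp,
      n_rna = length(rna), n_dna = length(dna), n_both = length(both),
      frac_rna = length(rna) / inoculum_size,
      frac_dna = length(dna) / inoculum_size,
      frac_both = length(both) / inoculum_size,
      rna_ids = list(sort(rna)), dna_ids = list(sort(dna)),
      both_ids = list(sort(both))
    )
  })
  dplyr::bind_rows(out)
}

#' Correlate RNA- and DNA-based strain abundances
#'
#' Correlates log-transformed mean relative abundance across the strains
#' detected by both methods. A pseudo-count of half the smallest nonzero
#' mean RA is added before the log transform.
#'
#' @param rna_profile,dna_profile Abundance-profile tibbles (`strain_id`,
#'   `sample`, `ra`).
#' @param shared_strains Strains detected by both methods.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble: `method`, `r`, `pvalue`, `n`.
#' @export
correlate_abundances <- function(rna_profile, dna_profile, shared_strains,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(shared_strains) < 3L) {
    stop("need at least 3 shared strains", call. = FALSE)
  }
  mean_ra <- function(profile) {
    profile |>
      dplyr::filter(.data$strain_id %in% shared_strains) |>
      dplyr::group_by(.data$strain_id) |>
      dplyr::summarise(mean_ra = mean(.data$ra, na.rm = TRUE), .groups = "drop")
  }
  a <- mean_ra(rna_profile); b <- mean_ra(dna_profile)
  tbl <- dplyr::inner_join(a, b, by = "strain_id", suffix = c("_rna", "_dna"))
  logt <- function(v) {
    nz <- v[v > 0]
    pc <- if (length(nz)) min(nz) / 2 else 1e-6
    log(v + pc)
  }
  x <- logt(tbl$mean_ra_rna); y <- logt(tbl$mean_ra_dna)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the abundance vectors", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(method = method, r = unname(ct$estimate), pvalue = ct$p.value,
                 n = nrow(tbl))
}
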