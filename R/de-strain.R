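#' Per-strain differential expression between root and matrix
#'
#' Runs the full NB pipeline ([run_de()]) independently for each focal
#' strain's gene (or orthogroup) set. Strains whose count tables cannot be
#' normalized (too few genes detected in every sample) are reported as
#' ineligible with the reason rather than dropped silently. Optionally, a set
#' of user-designated housekeeping genes is checked: stable genes are
#' expected to show no differential regulation, so any housekeeping gene
#' called DE is flagged in the QC report.
#'
#' @param per_strain Wide per-strain count tibble from [resolve_duplicates()]
#'   or [aggregate_by_og()] (needs `strain_id`).
#' @param samples Sample metadata tibble (`sample`, `compartment`).
#' @param focal_strains Strains to analyze (default: all in the table).
#' @param min_ref_genes Eligibility threshold (genes detected in all
#'   samples) per strain.
#' @param alpha_sig Significance level for the DEG call on adjusted p.
#' @param housekeeping_genes Optional character vector of stable gene ids for
#'   the QC check.
#' @return Object of class `strain_de_set`: `fits` (named list of
#'   `syncom_de`), `ineligible` (tibble: `strain_id`, `reason`),
#'   `housekeeping_qc` (tibble or NULL), `alpha_sig`. Use [tidy()] for one
#'   long result tibble and [glance()] for per-strain summaries.
#' @export
run_per_strain_de <- function(per_strain, samples, focal_strains = NULL,
                              min_ref_genes = 10, alpha_sig = 0.05,
                              housekeeping_genes = NULL) {
  stopifnot("strain_id" %in% names(per_strain))
  if (!all(c("root", "matrix") %in% samples$compartment)) {
    stop("both compartments must be present in `samples`", call. = FALSE)
  }
  if (is.null(focal_strains)) focal_strains <- unique(per_strain$strain_id)

  fits <- list()
  inel <- list()
  id_col <- if ("feature_id" %in% names(per_strain)) "feature_id" else "gene_id"
  for (s in focal_strains) {
    sub <- per_strain[per_strain$strain_id == s,
                      c(id_col, intersect(names(per_strain), samples$sample))]
    fit <- tryCatch(
      run_de(sub, samples, min_ref_genes = min_ref_genes, alpha_sig = alpha_sig),
      syncomtx_ineligible = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      inel[[s]] <- tibble::tibble(strain_id = s, reason = fit)
    } else {
      fits[[s]] <- fit
    }
  }

  hk <- NULL
  if (!is.null(housekeeping_genes) && length(fits) > 0L) {
    hk <- dplyr::bind_rows(lapply(names(fits), function(s) {
      res <- fits[[s]]$result
      res <- res[res$feature_id %in% housekeeping_genes, ]
      if (nrow(res) == 0L) return(NULL)
      tibble::tibble(strain_id = s, feature_id = res$feature_id,
                     log2fc_shrunk = res$log2fc_shrunk, padj = res$padj,
                     flagged = !is.na(res$padj) & res$padj < alpha_sig)
    }))
    if (!is.null(hk) && nrow(hk) > 0L && any(hk$flagged)) {
      warning(sum(hk$flagged),
              " housekeeping gene(s) called differentially expressed",
              call. = FALSE)
    }
  }

  structure(list(fits = fits,
                 ineligible = if (length(inel)) dplyr::bind_rows(inel) else
                   tibble::tibble(strain_id = character(0), reason = character(0)),
                 housekeeping_qc = hk,
                 alpha_sig = alpha_sig),
            class = "strain_de_set")
}

#' @export
print.strain_de_set <- function(x, ...) {
  cat("<strain_de_set> ", length(x$fits), " strain(s) tested, ",
      nrow(x$ineligible), " ineligible\n", sep = "")
  invisible(x)
}

#' @rdname run_per_strain_de
#' @param x A `strain_de_set`.
#' @param ... Unused.
#' @export
tidy.strain_de_set <- function(x, ...) {
  tested <- dplyr::bind_rows(lapply(names(x$fits), function(s)
    dplyr::mutate(x$fits[[s]]$result, strain_id = s, .before = 1)))
  if (nrow(x$ineligible) > 0L) {
    un <- dplyr::mutate(x$ineligible[, "strain_id", drop = FALSE],
                        feature_id = NA_character_, tested = FALSE,
                        deg = FALSE)
    tested <- dplyr::bind_rows(tested, un)
  }
  tested
}

#' @rdname run_per_strain_de
#' @export
glance.strain_de_set <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$fits), function(s)
    dplyr::mutate(glance(x$fits[[s]]), strain_id = s, .before = 1)))
}
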