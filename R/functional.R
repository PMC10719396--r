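#' Annotate orthogroups from their best representative member
#'
#' Each orthogroup inherits the functional labels (COG category, GO terms) of
#' one representative member gene: the member with the most annotation terms;
#' ties go to the longest sequence, then the lexicographically smallest
#' gene id. Orthogroups without any annotated member get category
#' `"unknown"` and no GO terms.
#'
#' @param catalog Catalog tibble (needs `gene_id`, `orthogroup_id`,
#'   `cog_category`, `go_terms`, `length`).
#' @return Tibble: `orthogroup_id`, `representative_gene`, `cog_category`,
#'   `go_terms` (semicolon-joined).
#' @export
annotate_ogs <- function(catalog) {
  needed <- c("gene_id", "orthogroup_id", "cog_category", "go_terms", "length")
  stopifnot(all(needed %in% names(catalog)))
  tbl <- catalog[, needed]
  tbl$n_terms <- ifelse(nzchar(tbl$go_terms),
                        lengths(strsplit(tbl$go_terms, ";", fixed = TRUE)), 0L) +
    as.integer(!tbl$cog_category %in% c("unknown", "", NA))
  tbl |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::arrange(dplyr::desc(.data$n_terms), dplyr::desc(.data$length),
                   .data$gene_id, .by_group = TRUE) |>
    dplyr::summarise(
      representative_gene = dplyr::first(.data$gene_id),
      cog_category = ifelse(dplyr::first(.data$n_terms) == 0L, "unknown",
                            dplyr::first(.data$cog_category)),
      go_terms = ifelse(dplyr::first(.data$n_terms) == 0L, "",
                        dplyr::first(.data$go_terms)),
      .groups = "drop")
}

#' Fisher-exact GO/COG term enrichment with BH correction
#'
#' For each annotation term, tests whether the target set is enriched
#' relative to the universe with a one-sided Fisher exact test on the 2x2
#' table (target-with-term, target-without, rest-with, rest-without), then
#' adjusts across tested terms by Benjamini-Hochberg. Terms annotated on
#' fewer than `min_count` universe members are skipped.
#'
#' @param target Character vector of feature ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of tested feature ids.
#' @param annotations Tibble `feature_id` -> `term` (one row per
#'   feature-term pair; see [annotation_pairs()]).
#' @param min_count Minimum annotated universe members per term.
#' @param alpha_sig FDR threshold for the `enriched` flag.
#' @return Tibble: `term`, `n_target`, `n_universe`, `target_size`,
#'   `universe_size`, `pvalue`, `padj`, `enriched`.
#' @export
fisher_go_enrichment <- function(target, universe, annotations,
                                 min_count = 3, alpha_sig = 0.05) {
  target <- unique(target)
  universe <- unique(universe)
  if (!all(target %in% universe)) {
    stop("`target` must be a subset of `universe`", call. = FALSE)
  }
  ann <- annotations[annotations$feature_id %in% universe, ]
  term_n <- table(ann$term)
  terms <- names(term_n)[term_n >= min_count]
  if (length(terms) == 0L) {
    return(tibble::tibble(term = character(0), n_target = integer(0),
                          n_universe = integer(0), target_size = integer(0),
                          universe_size = integer(0), pvalue = numeric(0),
                          padj = numeric(0), enriched = logical(0)))
  }
  n_t <- length(unique(target))
  n_u <- length(unique(universe))
  res <- lapply(terms, function(tm) {
    with_term <- unique(ann$feature_id[ann$term == tm])
    a <- sum(target %in% with_term)
    k <- length(with_term)
    # one-sided enrichment p = P(X >= a), X ~ Hypergeom(n_u, k, n_t)
    p <- stats::phyper(a - 1, k, n_u - k, n_t, lower.tail = FALSE)
    tibble::tibble(term = tm, n_target = a, n_universe = k,
                   target_size = n_t, universe_size = n_u, pvalue = p)
  })
  out <- dplyr::bind_rows(res)
  out$padj <- bh_adjust(out$pvalue)
  out$enriched <- out$padj < alpha_sig
  dplyr::arrange(out, .data$pvalue, .data$term)
}

#' Expand semicolon-joined GO annotations to feature-term pairs
#'
#' @param annotated Tibble with an id column and a `go_terms` column
#'   (semicolon-joined).
#' @param id_col Name of the feature id column.
#' @return Tibble: `feature_id`, `term`.
#' @export
annotation_pairs <- function(annotated, id_col = "orthogroup_id") {
  terms <- strsplit(annotated$go_terms, ";", fixed = TRUE)
  n <- lengths(terms)
  out <- tibble::tibble(feature_id = rep(annotated[[id_col]], n),
                        term = unlist(terms, use.names = FALSE))
  out[nzchar(out$term), ]
}

#' Mean log2FC of top-ranked orthogroups by functional category and strain
#'
#' Entry (strain, category) is the mean shrunken log2FC, within that strain,
#' of the top-ranked orthogroups annotated with that COG category; categories
#' with no top orthogroup tested in a strain are NA.
#'
#' @param top_table Top slice from [cumulative_lfc_ranking()].
#' @param strain_og_de The `strain_de_set` behind the ranking.
#' @param og_annotation Tibble from [annotate_ogs()].
#' @return Tibble: `strain_id`, `cog_category`, `mean_log2fc`, `n_ogs`.
#' @export
category_mean_lfc <- function(top_table, strain_og_de, og_annotation) {
  long <- tidy(strain_og_de)
  long <- long[long$feature_id %in% top_table$orthogroup_id & long$tested, ]
  long <- dplyr::left_join(
    long, og_annotation[, c("orthogroup_id", "cog_category")],
    by = c(feature_id = "orthogroup_id"))
  long |>
    dplyr::filter(!is.na(.data$log2fc_shrunk)) |>
    dplyr::group_by(.data$strain_id, .data$cog_category) |>
    dplyr::summarise(mean_log2fc = mean(.data$log2fc_shrunk),
                     n_ogs = dplyr::n(), .groups = "drop")
}

#' Regress strain root abundance on a functional category's regulation
#'
#' Ordinary least squares of log-transformed mean root relative abundance on
#' the per-strain mean log2FC of one functional category (e.g. energy
#' production and conversion), quantifying how much of root colonization
#' success a function's regulation explains. Also returns the pairwise
#' Pearson correlogram between all category columns.
#'
#' @param cat_lfc Tibble from [category_mean_lfc()].
#' @param profile RNA abundance profile ([strain_relative_abundance()]).
#' @param samples Sample metadata tibble.
#' @param category COG category to regress on (default `"C"`).
#' @param pseudo_count Added to mean RA before log (default: half the
#'   smallest nonzero mean RA).
#' @return List of class `fn_abundance_fit`: `fit` (tibble: `slope`,
#'   `intercept`, `r_squared`, `pvalue`, `n`), `points` (per-strain data),
#'   `correlogram` (tibble: `cat_x`, `cat_y`, `r`, `pvalue`, `significant`).
#' @export
function_abundance_regression <- function(cat_lfc, profile, samples,
                                          category = "C",
                                          pseudo_count = NULL) {
  root_samples <- samples$sample[samples$compartment == "root"]
  ra <- profile |>
    dplyr::filter(.data$sample %in% root_samples) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(mean_root_ra = mean(.data$ra), .groups = "drop")
  if (is.null(pseudo_count)) {
    nz <- ra$mean_root_ra[ra$mean_root_ra > 0]
    pseudo_count <- if (length(nz)) min(nz) / 2 else 1e-6
  }
  ra$log_ra <- log(ra$mean_root_ra + pseudo_count)

  x <- cat_lfc[cat_lfc$cog_category == category, c("strain_id", "mean_log2fc")]
  pts <- dplyr::inner_join(x, ra, by = "strain_id")
  pts <- pts[stats::complete.cases(pts[, c("mean_log2fc", "log_ra")]), ]
  if (nrow(pts) < 3L) {
    stop("need at least 3 strains with a defined category mean log2FC",
         call. = FALSE)
  }
  lmfit <- stats::lm(log_ra ~ mean_log2fc, data = pts)
  sm <- summary(lmfit)
  fit <- tibble::tibble(
    slope = unname(stats::coef(lmfit)[2]),
    intercept = unname(stats::coef(lmfit)[1]),
    r_squared = sm$r.squared,
    pvalue = sm$coefficients[2, 4],
    n = nrow(pts)
  )

  wide <- tidyr::pivot_wider(cat_lfc[, c("strain_id", "cog_category", "mean_log2fc")],
                             names_from = "cog_category",
                             values_from = "mean_log2fc")
  cats <- setdiff(names(wide), "strain_id")
  cg <- list()
  for (i in seq_along(cats)) for (j in seq_along(cats)) {
    xi <- wide[[cats[i]]]; xj <- wide[[cats[j]]]
    ok <- stats::complete.cases(xi, xj)
    if (sum(ok) >= 3 && stats::sd(xi[ok]) > 0 && stats::sd(xj[ok]) > 0) {
      ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
      cg[[length(cg) + 1L]] <- tibble::tibble(
        cat_x = cats[i], cat_y = cats[j], r = unname(ct$estimate),
        pvalue = ct$p.value, significant = ct$p.value < 0.05)
    }
  }
  structure(list(fit = fit, points = pts,
                 correlogram = dplyr::bind_rows(cg), category = category),
            class = "fn_abundance_fit")
}

#' @export
print.fn_abundance_fit <- function(x, ...) {
  cat("<fn_abundance_fit> category ", x$category, ": R^2 = ",
      signif(x$fit$r_squared, 4), ", p = ", signif(x$fit$pvalue, 3),
      " (n = ", x$fit$n, ")\n", sep = "")
  invisible(x)
}

#' @rdname function_abundance_regression
#' @param x An `fn_abundance_fit`.
#' @param ... Unused.
#' @export
tidy.fn_abundance_fit <- function(x, ...) x$fit

#' @rdname function_abundance_regression
#' @export
glance.fn_abundance_fit <- function(x, ...) x$fit
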