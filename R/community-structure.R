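#' Relative orthogroup counts per strain-sample transcriptome unit
#'
#' Each strain-by-sample transcriptome becomes one unit: a row of orthogroup
#' relative read counts summing to 1. All-zero units are dropped with a
#' message.
#'
#' @param og_counts Wide per-strain orthogroup count tibble
#'   ([aggregate_by_og()]).
#' @param samples Sample metadata tibble.
#' @return List: `table` (matrix units x orthogroups, rows sum to 1),
#'   `units` (tibble: `unit`, `strain_id`, `sample`, `compartment`).
#' @export
og_relative_counts <- function(og_counts, samples) {
  smp <- intersect(names(og_counts), samples$sample)
  long <- og_counts |>
    tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample",
                        values_to = "count") |>
    dplyr::mutate(unit = paste(.data$strain_id, .data$sample, sep = "."))
  wide <- long |>
    dplyr::select("unit", "feature_id", "count") |>
    tidyr::pivot_wider(names_from = "feature_id", values_from = "count",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$unit
  tot <- rowSums(m)
  if (any(tot == 0)) {
    message("dropping ", sum(tot == 0), " all-zero transcriptome unit(s): ",
            paste(utils::head(rownames(m)[tot == 0], 5), collapse = ", "))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  m <- m / tot
  units <- tibble::tibble(unit = rownames(m)) |>
    tidyr::separate_wider_delim("unit", ".", names = c("strain_id", "sample"),
                                cols_remove = FALSE) |>
    dplyr::left_join(samples[, c("sample", "compartment")], by = "sample") |>
    dplyr::select("unit", "strain_id", "sample", "compartment")
  list(table = m, units = units)
}

#' Bray-Curtis dissimilarity between transcriptome units
#'
#' \eqn{d(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}.
#'
#' @param table Non-negative matrix, units in rows.
#' @return A symmetric `dist`-convertible matrix with zero diagonal and
#'   entries in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  if (any(table < 0)) stop("rows must be non-negative", call. = FALSE)
  if (sum(rowSums(table) == 0) >= 2L) {
    stop("distance undefined between all-zero rows", call. = FALSE)
  }
  as.matrix(vegan::vegdist(table, method = "bray"))
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical scaling: the squared dissimilarities are double-centred
#' (-1/2 d^2), eigendecomposed, and the axes with positive eigenvalues kept;
#' coordinates are eigenvectors scaled by the square-root eigenvalues.
#' Negative eigenvalues (non-Euclidean dissimilarities) are reported, not
#' corrected.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param n_axes Number of axes requested (fewer are returned, with a
#'   warning, when fewer positive eigenvalues exist).
#' @return List of class `pcoa_ordination`: `coordinates` (tibble: `unit`,
#'   `axis_1`, ...), `eigenvalues`, `variance_explained` (percent of the
#'   positive-eigenvalue total).
#' @export
pcoa_ordination <- function(d, n_axes = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE))
  eig <- cs$eig
  pos <- min(sum(eig > 1e-10), ncol(cs$points))
  if (pos == 0L) {
    # degenerate configuration (all points coincide): everything at the origin
    coords <- matrix(0, n, n_axes)
  } else {
    if (n_axes > pos) {
      warning("only ", pos, " positive eigenvalue(s); returning ", pos,
              " axis/axes", call. = FALSE)
      n_axes <- pos
    }
    coords <- cs$points[, seq_len(n_axes), drop = FALSE]
  }
  colnames(coords) <- paste0("axis_", seq_len(n_axes))
  out <- tibble::as_tibble(coords)
  out <- dplyr::mutate(out, unit = rownames(dm) %||% as.character(seq_len(n)),
                       .before = 1)
  tot_pos <- sum(pmax(eig, 0))
  structure(list(
    coordinates = out,
    eigenvalues = eig,
    variance_explained = if (tot_pos > 0) {
      100 * pmax(eig, 0)[seq_len(n_axes)] / tot_pos
    } else rep(0, n_axes)
  ), class = "pcoa_ordination")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gower-centred inner-product matrix of squared dissimilarities
gower_matrix <- function(dm) {
  a <- -0.5 * dm^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# hat matrices of the sequential (type-I) decomposition: one per cumulative
# model, starting from the intercept-only model
permanova_hats <- function(mf, terms) {
  n <- nrow(mf)
  hats <- list(matrix(1 / n, n, n))
  ranks <- 1L
  for (i in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(i)]), mf)
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[i + 1L]] <- tcrossprod(Q)
    ranks <- c(ranks, qrX$rank)
  }
  list(hats = hats, df = diff(ranks), df_resid = n - ranks[length(ranks)])
}

# sequential SS of a (permuted) Gower matrix given precomputed hats;
# tr(H G) = sum(H * G) since both are symmetric
permanova_ss <- function(G, hp) {
  tr_h <- vapply(hp$hats, function(h) sum(h * G), numeric(1))
  ss <- diff(tr_h)
  ss_total <- sum(diag(G))
  list(ss = ss, df = hp$df, ss_resid = ss_total - tr_h[length(tr_h)],
       df_resid = hp$df_resid, ss_total = ss_total)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the variance of a dissimilarity matrix (via the Gower-centred
#' inner-product decomposition) across model terms with sequential (type-I)
#' sums of squares, and tests each term's pseudo-F against free permutations
#' of the unit labels: \eqn{p = (1 + \#\{F^{perm} \ge F^{obs}\})/(1 + n_{perm})},
#' so the identity permutation always counts and p is never 0. With
#' `exhaustive = TRUE` all `n!` label permutations are enumerated instead
#' (small n only) and \eqn{p = \#\{F^{perm} \ge F^{obs}\}/n!}.
#'
#' @param d Dissimilarity matrix (units x units).
#' @param units Tibble of per-unit factors, rows aligned with `d`.
#' @param terms Character vector of model terms in decomposition order, e.g.
#'   `c("compartment", "strain_id", "compartment:strain_id")`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return Tibble of class `permanova_result`: `term`, `df`, `ss`, `f`,
#'   `r_squared`, `pvalue`, plus residual and total rows; `n_perm` as an
#'   attribute.
#' @export
permanova <- function(d, units, terms, n_perm = 999, seed = 1,
                      exhaustive = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(nrow(units) == n)
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  mf <- as.data.frame(units[, base_vars, drop = FALSE])
  for (v in base_vars) {
    mf[[v]] <- factor(mf[[v]])
    if (nlevels(mf[[v]]) < 2L) {
      stop("factor `", v, "` has fewer than 2 levels", call. = FALSE)
    }
    if (nlevels(mf[[v]]) == n) {
      stop("factor `", v, "` is confounded with units (one unit per level)",
           call. = FALSE)
    }
  }
  if (!exhaustive && n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)

  G <- gower_matrix(dm)
  hp <- permanova_hats(mf, terms)
  obs <- permanova_ss(G, hp)
  f_obs <- (obs$ss / obs$df) / (obs$ss_resid / obs$df_resid)

  perms <- if (exhaustive) {
    all_perms(n)
  } else {
    set.seed(seed)
    lapply(seq_len(n_perm), function(i) sample.int(n))
  }

  exceed <- numeric(length(terms))
  for (p in perms) {
    Gp <- G[p, p]
    ssp <- permanova_ss(Gp, hp)
    fp <- (ssp$ss / ssp$df) / (ssp$ss_resid / ssp$df_resid)
    exceed <- exceed + (fp >= f_obs - 1e-12)
  }
  pval <- if (exhaustive) exceed / length(perms) else
    (1 + exceed) / (1 + length(perms))

  out <- tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(obs$df, obs$df_resid, n - 1),
    ss = c(obs$ss, obs$ss_resid, obs$ss_total),
    f = c(f_obs, NA, NA),
    r_squared = c(obs$ss, obs$ss_resid, obs$ss_total) / obs$ss_total,
    pvalue = c(pval, NA, NA)
  )
  attr(out, "n_perm") <- length(perms)
  class(out) <- c("permanova_result", class(out))
  out
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}
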