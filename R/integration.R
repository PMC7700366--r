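#' Per-gene DNA score
#'
#' Mean of a gene's per-cancer average copy-number scores: one number per
#' gene summarizing whether it trends towards amplification (> 0) or
#' deletion (< 0) across the cohort.
#'
#' @param gistic_row Numeric vector of per-cancer mean copy-number scores.
#' @return A single numeric.
#' @export
dna_score <- function(gistic_row) {
  if (length(gistic_row) == 0) abort("empty score row")
  mean(gistic_row)
}

#' Per-gene mRNA score
#'
#' Number of cancers significantly upregulating the gene minus the number
#' significantly downregulating it; positive = net upregulated in cancer.
#'
#' @param n_up,n_down Non-negative counts.
#' @return Integer score.
#' @export
mrna_score <- function(n_up, n_down) {
  if (any(n_up < 0) || any(n_down < 0)) abort("counts must be non-negative")
  as.integer(n_up - n_down)
}

#' Per-gene survival score
#'
#' Number of cancers where high expression is significantly unfavorable
#' minus the number where it is significantly favorable; positive = net
#' unfavorable.
#'
#' @param n_unfavorable,n_favorable Non-negative counts.
#' @return Integer score.
#' @export
survival_score <- function(n_unfavorable, n_favorable) {
  if (any(n_unfavorable < 0) || any(n_favorable < 0)) {
    abort("counts must be non-negative")
  }
  as.integer(n_unfavorable - n_favorable)
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant column maps to 0.5 everywhere
#' (a neutral contribution that avoids division by zero).
#'
#' @param column Numeric vector.
#' @return Numeric vector in \[0, 1\], order-preserving.
#' @export
minmax_normalize <- function(column) {
  if (length(column) == 0) abort("empty column")
  rng <- range(column)
  if (rng[1] == rng[2]) return(rep(0.5, length(column)))
  (column - rng[1]) / (rng[2] - rng[1])
}

#' Composite score and gene ranking
#'
#' Min-max normalizes the three raw score columns, averages them with equal
#' weight into a composite in \[0, 1\], and ranks genes by ascending
#' composite: rank 1 is the most favorable (most cancer-inhibiting) gene,
#' the last rank the most cancer-promoting. Ties are broken alphabetically.
#'
#' @param scores Tibble with columns `gene`, `dna_score`, `mrna_score`,
#'   `survival_score` (>= 2 genes).
#' @return An `aars_ranking` with a tibble `scores` adding `norm_dna`,
#'   `norm_mrna`, `norm_survival`, `composite` and `rank`, sorted by rank.
#' @export
composite_rank <- function(scores) {
  needed <- c("gene", "dna_score", "mrna_score", "survival_score")
  if (!all(needed %in% names(scores))) {
    abort(paste0("scores needs columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(scores) < 2) {
    abort("ranking needs at least 2 genes (normalization undefined)")
  }
  if (anyDuplicated(scores$gene)) abort("duplicate gene symbols in scores")
  out <- scores |>
    dplyr::mutate(
      norm_dna = minmax_normalize(.data$dna_score),
      norm_mrna = minmax_normalize(.data$mrna_score),
      norm_survival = minmax_normalize(.data$survival_score),
      composite = (.data$norm_dna + .data$norm_mrna + .data$norm_survival) / 3
    ) |>
    dplyr::arrange(.data$composite, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(scores = out), class = "aars_ranking")
}

#' @export
print.aars_ranking <- function(x, n = 5, ...) {
  s <- x$scores
  cat("<aars_ranking> ", nrow(s), " genes; most favorable: ",
      paste(head(s$gene, n), collapse = ", "),
      "; most unfavorable: ",
      paste(rev(utils::tail(s$gene, n)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.aars_ranking <- function(x, ...) x$scores

#' @exportS3Method
glance.aars_ranking <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$scores),
    most_favorable = x$scores$gene[1],
    most_unfavorable = x$scores$gene[nrow(x$scores)],
    composite_min = min(x$scores$composite),
    composite_max = max(x$scores$composite)
  )
}

#' Pearson correlation between two score columns
#'
#' @param col_a,col_b Numeric vectors of equal length >= 3.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Tibble with `pearson_r`, `p_value`, `significant`, `n`.
#' @export
cross_level_correlation <- function(col_a, col_b, alpha = 0.05) {
  if (length(col_a) != length(col_b)) abort("columns must have equal length")
  if (length(col_a) < 3) abort("need at least 3 observations")
  if (stats::sd(col_a) == 0 || stats::sd(col_b) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble::tibble(pearson_r = NA_real_, p_value = NA_real_,
                          significant = NA, n = length(col_a)))
  }
  ct <- cor.test(col_a, col_b, method = "pearson")
  tibble::tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 significant = ct$p.value < alpha, n = length(col_a))
}

#' Pairwise correlations between the three score levels
#'
#' @param scores Tibble with `dna_score`, `mrna_score`, `survival_score`
#'   columns (raw, one row per gene).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Tibble, one row per pair (dna-mrna, mrna-survival, dna-survival).
#' @export
cross_level_correlations <- function(scores, alpha = 0.05) {
  pairs <- list(c("dna_score", "mrna_score"),
                c("mrna_score", "survival_score"),
                c("dna_score", "survival_score"))
  purrr::map_dfr(pairs, function(p) {
    dplyr::bind_cols(tibble::tibble(pair = paste(sub("_score", "", p),
                                                 collapse = "-")),
                     cross_level_correlation(scores[[p[1]]], scores[[p[2]]],
                                             alpha = alpha))
  })
}

#' Assemble the per-gene score table from the three analysis maps
#'
#' @param heatmap Wide gene-by-cancer tibble from [gistic_heatmap()].
#' @param de An `aars_de_map`.
#' @param surv An `aars_surv_map`.
#' @return Tibble with `gene` and the three raw scores, registry row order.
#' @export
integration_scores <- function(heatmap, de, surv) {
  tibble::tibble(
    gene = heatmap$gene,
    dna_score = apply(heatmap[, -1, drop = FALSE], 1, dna_score)
  ) |>
    dplyr::left_join(de$totals, by = "gene") |>
    dplyr::left_join(surv$totals, by = "gene") |>
    dplyr::mutate(
      mrna_score = mrna_score(.data$n_up, .data$n_down),
      survival_score = survival_score(.data$n_unfavorable, .data$n_favorable)
    ) |>
    dplyr::select("gene", "dna_score", "mrna_score", "survival_score")
}
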