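#' Log2 fold change between tumor and normal cohorts
#'
#' Computed as the difference of group means on the log2(TPM + 1) scale
#' (tumor minus normal). The pseudo-count keeps zero expression defined.
#'
#' @param tumor,normal Non-negative expression vectors (TPM-like).
#' @return A single numeric log2 fold change.
#' @export
log2_fold_change <- function(tumor, normal) {
  if (length(tumor) == 0 || length(normal) == 0) {
    abort("tumor and normal vectors must be non-empty")
  }
  if (any(tumor < 0) || any(normal < 0)) {
    abort("expression values must be non-negative")
  }
  mean(log2(tumor + 1)) - mean(log2(normal + 1))
}

#' Two-group ANOVA test of differential expression
#'
#' A one-way ANOVA F-test (pooled variance; with two groups equivalent to the
#' squared pooled two-sample t statistic) comparing tumor against normal on
#' the log2(TPM + 1) scale. Degenerate input with zero within-group variance
#' in both groups yields p = 1 when the group means coincide and p = 0
#' otherwise.
#'
#' @param tumor,normal Expression vectors, each of length >= 2.
#' @param log_transform Apply the log2(x + 1) transform first (default TRUE;
#'   set FALSE if the inputs are already on the analysis scale).
#' @return The two-sided p-value.
#' @export
de_test <- function(tumor, normal, log_transform = TRUE) {
  if (length(tumor) < 2 || length(normal) < 2) {
    abort("each group needs at least 2 samples")
  }
  if (log_transform) {
    tumor <- log2(tumor + 1)
    normal <- log2(normal + 1)
  }
  if (!all(is.finite(tumor)) || !all(is.finite(normal))) {
    abort("expression values must be finite")
  }
  if (stats::var(tumor) == 0 && stats::var(normal) == 0) {
    return(if (mean(tumor) == mean(normal)) 1 else 0)
  }
  x <- c(tumor, normal)
  g <- factor(rep(c("tumor", "normal"), c(length(tumor), length(normal))))
  oneway.test(x ~ g, var.equal = TRUE)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: sort p ascending, q(i) = min over j >= i of
#' p(j) * m / j capped at 1, returned in input order.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

de_call <- function(log2fc, q_value, fc_threshold, q_threshold) {
  lfc_gate <- log2(fc_threshold)
  dplyr::case_when(
    log2fc >= lfc_gate & q_value <= q_threshold ~ "up",
    log2fc <= -lfc_gate & q_value <= q_threshold ~ "down",
    TRUE ~ "ns"
  )
}

#' Tumor-vs-normal differential-expression map
#'
#' For every registry gene and every cancer with both cohorts available,
#' computes the log2 fold change and ANOVA p-value, applies
#' Benjamini-Hochberg adjustment within each cancer across the gene panel,
#' and calls `up` / `down` / `ns` with the dual gate: at least a
#' `fc_threshold`-fold change on the linear scale (i.e. |log2FC| >=
#' log2(`fc_threshold`)) and q <= `q_threshold`. Cancers lacking a normal
#' cohort are marked not evaluable and excluded from the per-gene totals,
#' with a warning.
#'
#' @param cohort An `aars_cohort`.
#' @param registry Gene registry tibble (row order fixes map row order).
#' @param cancers Cancer-table tibble; cancers ordered by ascending median
#'   overall survival in all outputs.
#' @param fc_threshold Linear fold-change gate (default 1.5).
#' @param q_threshold FDR gate (default 0.05).
#' @return An `aars_de_map`: list with `results` (tibble gene, cancer,
#'   log2fc, p_value, q_value, call), `totals` (tibble gene, n_up, n_down),
#'   `cancer_order`, `not_evaluable`, and the thresholds.
#' @export
de_map <- function(cohort, registry, cancers, fc_threshold = 1.5,
                   q_threshold = 0.05) {
  cancers <- dplyr::filter(cancers, .data$abbreviation %in% cohort$cancers)
  ordered <- sort_cancers_by_os(cancers)$abbreviation
  genes <- registry$symbol

  evaluable <- vapply(ordered, function(cancer) {
    nrm <- cohort$data[[cancer]]$expr_normal
    !is.null(nrm) && ncol(nrm) > 1
  }, logical(1))
  if (any(!evaluable)) {
    warn(paste0("no normal cohort for: ",
                paste(ordered[!evaluable], collapse = ", "),
                "; column(s) not evaluable"))
  }

  results <- purrr::map_dfr(ordered[evaluable], function(cancer) {
    tum <- gene_tbl_to_mat(cohort$data[[cancer]]$expr_tumor)
    nrm <- gene_tbl_to_mat(cohort$data[[cancer]]$expr_normal)
    absent <- setdiff(genes, intersect(rownames(tum), rownames(nrm)))
    if (length(absent) > 0) {
      abort(paste0("gene(s) missing from expression matrices of ", cancer,
                   ": ", paste(absent, collapse = ", ")))
    }
    p <- vapply(genes, function(g) de_test(tum[g, ], nrm[g, ]), numeric(1))
    lfc <- vapply(genes, function(g) log2_fold_change(tum[g, ], nrm[g, ]),
                  numeric(1))
    q <- bh_adjust(p)
    tibble::tibble(gene = genes, cancer = cancer, log2fc = lfc,
                   p_value = p, q_value = q,
                   call = de_call(lfc, q, fc_threshold, q_threshold))
  })

  totals <- results |>
    dplyr::group_by(gene = factor(.data$gene, levels = genes)) |>
    dplyr::summarise(n_up = sum(.data$call == "up"),
                     n_down = sum(.data$call == "down"),
                     .groups = "drop") |>
    dplyr::mutate(gene = as.character(.data$gene))
  if (nrow(results) == 0) {
    totals <- tibble::tibble(gene = genes, n_up = 0L, n_down = 0L)
  }

  structure(list(results = results, totals = totals,
                 cancer_order = ordered,
                 not_evaluable = ordered[!evaluable],
                 fc_threshold = fc_threshold, q_threshold = q_threshold),
            class = "aars_de_map")
}

#' @export
print.aars_de_map <- function(x, ...) {
  cat("<aars_de_map> ", length(unique(x$results$gene)), " genes x ",
      length(x$cancer_order), " cancers; ",
      sum(x$results$call == "up"), " up / ",
      sum(x$results$call == "down"), " down calls ",
      "(|FC| >= ", x$fc_threshold, ", q <= ", x$q_threshold, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.aars_de_map <- function(x, ...) x$results

#' @exportS3Method
glance.aars_de_map <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$results$gene)),
    n_cancers = length(x$cancer_order),
    n_not_evaluable = length(x$not_evaluable),
    n_up = sum(x$results$call == "up"),
    n_down = sum(x$results$call == "down"),
    fc_threshold = x$fc_threshold,
    q_threshold = x$q_threshold
  )
}
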