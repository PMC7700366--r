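#' Median split of per-sample expression
#'
#' Samples strictly above the median are labelled `high`; samples at or below
#' the median (including ties at the median) are labelled `low`.
#'
#' @param values Numeric expression values, one per sample (>= 4 samples).
#' @return Character vector of `"high"` / `"low"` labels, same order.
#' @export
median_split <- function(values) {
  if (length(values) < 4) abort("median split needs at least 4 samples")
  if (length(unique(values)) == 1) {
    abort("degenerate split: all expression values identical")
  }
  ifelse(values > median(values), "high", "low")
}

check_survival_table <- function(table) {
  needed <- c("sample_id", "time_months", "event")
  if (!all(needed %in% names(table))) {
    abort(paste0("survival table needs columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (nrow(table) == 0) abort("survival table is empty")
  if (any(table$time_months <= 0)) abort("survival times must be positive")
  if (anyDuplicated(table$sample_id)) {
    abort("duplicate sample ids in survival table")
  }
  invisible(table)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param table Survival tibble (`sample_id`, `time_months`, `event` logical
#'   or 0/1, TRUE = death observed).
#' @return A tibble, one row per distinct observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor` and the product-limit `survival` probability.
#' @export
km_estimate <- function(table) {
  check_survival_table(table)
  fit <- survival::survfit(
    survival::Surv(table$time_months, as.logical(table$event)) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 survival = fit$surv)
}

surv_diff_fit <- function(group_high, group_low) {
  check_survival_table(group_high)
  check_survival_table(group_low)
  time <- c(group_high$time_months, group_low$time_months)
  event <- as.logical(c(group_high$event, group_low$event))
  group <- rep(c("high", "low"), c(nrow(group_high), nrow(group_low)))
  if (sum(event) == 0) return(NULL)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  idx_high <- which(grepl("high", names(sd$n)))
  list(chisq = sd$chisq,
       obs = c(high = sd$obs[idx_high], low = sd$obs[-idx_high]),
       exp = c(high = sd$exp[idx_high], low = sd$exp[-idx_high]))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of the high- versus low-expression groups:
#' observed against expected deaths under the hypergeometric null at each
#' distinct event time, chi-square with 1 degree of freedom. When no deaths
#' are observed at all the test is vacuous and `(0, 1)` is returned.
#'
#' @param group_high,group_low Survival tibbles for the two groups.
#' @return A list with `chi_square` and `p_value`.
#' @export
logrank_test <- function(group_high, group_low) {
  fit <- surv_diff_fit(group_high, group_low)
  if (is.null(fit)) return(list(chi_square = 0, p_value = 1))
  list(chi_square = unname(fit$chisq),
       p_value = unname(pchisq(fit$chisq, df = 1, lower.tail = FALSE)))
}

#' Mantel-Haenszel hazard ratio (high vs low expression)
#'
#' `(O_high / E_high) / (O_low / E_low)`, with observed and expected deaths
#' accumulated from the log-rank tabulation. HR > 1 means high expression is
#' unfavorable. When either group has zero observed deaths the ratio is not
#' supported by the data and `NA` is returned.
#'
#' @param group_high,group_low Survival tibbles for the two groups.
#' @return A positive numeric, or `NA_real_` when undefined.
#' @export
hazard_ratio <- function(group_high, group_low) {
  fit <- surv_diff_fit(group_high, group_low)
  if (is.null(fit) || fit$obs[["high"]] == 0 || fit$obs[["low"]] == 0) {
    return(NA_real_)
  }
  unname((fit$obs[["high"]] / fit$exp[["high"]]) /
           (fit$obs[["low"]] / fit$exp[["low"]]))
}

#' Expression-stratified survival map
#'
#' For every registry gene and every cancer with a survival table, splits the
#' tumor cohort at the gene's median expression, runs the log-rank test and
#' computes the Mantel-Haenszel hazard ratio. Benjamini-Hochberg adjustment
#' is applied globally across all evaluable cells of the map (the map is
#' thresholded as one experiment). A cell is `unfavorable` when HR > 1 and
#' q <= `q_threshold`, `favorable` when HR < 1 and q <= `q_threshold`, `ns`
#' otherwise; cells with a degenerate split or an undefined HR are excluded
#' from the per-gene direction totals.
#'
#' @param cohort An `aars_cohort`.
#' @param registry Gene registry tibble.
#' @param cancers Cancer-table tibble.
#' @param q_threshold FDR gate (default 0.05).
#' @return An `aars_surv_map`: list with `results` (gene, cancer,
#'   hazard_ratio, logrank_p, q_value, direction, n_high, n_low, evaluable),
#'   `totals` (gene, n_unfavorable, n_favorable), `cancer_order`,
#'   `not_evaluable` cancers and `q_threshold`.
#' @export
survival_map <- function(cohort, registry, cancers, q_threshold = 0.05) {
  cancers <- dplyr::filter(cancers, .data$abbreviation %in% cohort$cancers)
  ordered <- sort_cancers_by_os(cancers)$abbreviation
  genes <- registry$symbol

  has_surv <- vapply(ordered, function(cancer) {
    !is.null(cohort$data[[cancer]]$survival)
  }, logical(1))
  if (any(!has_surv)) {
    warn(paste0("no survival table for: ",
                paste(ordered[!has_surv], collapse = ", "),
                "; column(s) not evaluable"))
  }

  results <- purrr::map_dfr(ordered[has_surv], function(cancer) {
    d <- cohort$data[[cancer]]
    expr <- gene_tbl_to_mat(d$expr_tumor)
    surv <- d$survival
    expr <- expr[, surv$sample_id, drop = FALSE]
    purrr::map_dfr(genes, function(g) {
      vals <- expr[g, ]
      if (length(unique(vals)) == 1) {
        return(tibble::tibble(gene = g, cancer = cancer,
                              hazard_ratio = NA_real_, logrank_p = NA_real_,
                              n_high = NA_integer_, n_low = NA_integer_,
                              evaluable = FALSE))
      }
      grp <- median_split(vals)
      hi <- surv[grp == "high", ]
      lo <- surv[grp == "low", ]
      lr <- logrank_test(hi, lo)
      tibble::tibble(gene = g, cancer = cancer,
                     hazard_ratio = hazard_ratio(hi, lo),
                     logrank_p = lr$p_value,
                     n_high = nrow(hi), n_low = nrow(lo), evaluable = TRUE)
    })
  })

  if (nrow(results) > 0) {
    results$q_value <- NA_real_
    results$q_value[results$evaluable] <-
      bh_adjust(results$logrank_p[results$evaluable])
    results$direction <- dplyr::case_when(
      !results$evaluable | is.na(results$hazard_ratio) ~ "ns",
      results$hazard_ratio > 1 & results$q_value <= q_threshold ~ "unfavorable",
      results$hazard_ratio < 1 & results$q_value <= q_threshold ~ "favorable",
      TRUE ~ "ns"
    )
  } else {
    results <- tibble::tibble(gene = character(), cancer = character(),
                              hazard_ratio = double(), logrank_p = double(),
                              n_high = integer(), n_low = integer(),
                              evaluable = logical(), q_value = double(),
                              direction = character())
  }

  totals <- results |>
    dplyr::group_by(gene = factor(.data$gene, levels = genes)) |>
    dplyr::summarise(n_unfavorable = sum(.data$direction == "unfavorable"),
                     n_favorable = sum(.data$direction == "favorable"),
                     .groups = "drop") |>
    dplyr::mutate(gene = as.character(.data$gene))
  if (nrow(results) == 0) {
    totals <- tibble::tibble(gene = genes, n_unfavorable = 0L,
                             n_favorable = 0L)
  }

  structure(list(results = results, totals = totals, cancer_order = ordered,
                 not_evaluable = ordered[!has_surv],
                 q_threshold = q_threshold),
            class = "aars_surv_map")
}

#' @export
print.aars_surv_map <- function(x, ...) {
  cat("<aars_surv_map> ", length(unique(x$results$gene)), " genes x ",
      length(x$cancer_order), " cancers; ",
      sum(x$results$direction == "unfavorable"), " unfavorable / ",
      sum(x$results$direction == "favorable"), " favorable cells ",
      "(q <= ", x$q_threshold, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.aars_surv_map <- function(x, ...) x$results

#' @exportS3Method
glance.aars_surv_map <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$results$gene)),
    n_cancers = length(x$cancer_order),
    n_cells_evaluable = sum(x$results$evaluable),
    n_unfavorable = sum(x$results$direction == "unfavorable"),
    n_favorable = sum(x$results$direction == "favorable"),
    q_threshold = x$q_threshold
  )
}

#' Correlation of cancer aggressiveness with panel upregulation
#'
#' Pearson correlation between each cancer's median overall survival and the
#' number of panel genes it differentially upregulates, with a two-sided
#' p-value from the t transform on n - 2 degrees of freedom. A negative r
#' supports the reading that more aggressive (shorter-survival) cancers
#' upregulate more of the panel. Cancers with incompatible normal controls
#' can be excluded by abbreviation.
#'
#' @param cancers Cancer-table tibble.
#' @param up_counts Tibble with columns `cancer` and `n_up` (per-cancer count
#'   of upregulated panel genes), e.g. from [de_up_counts_by_cancer()].
#' @param exclude Character vector of cancer abbreviations to drop.
#' @return A tibble with `pearson_r`, `p_value` and `n`.
#' @export
aggressiveness_correlation <- function(cancers, up_counts, exclude = NULL) {
  merged <- dplyr::inner_join(
    dplyr::select(cancers, cancer = "abbreviation", "median_os_months"),
    up_counts, by = "cancer")
  if (!is.null(exclude)) {
    merged <- dplyr::filter(merged, !.data$cancer %in% exclude)
  }
  if (nrow(merged) < 3) abort("need at least 3 cancers for a correlation")
  if (stats::sd(merged$median_os_months) == 0 || stats::sd(merged$n_up) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble::tibble(pearson_r = NA_real_, p_value = NA_real_,
                          n = nrow(merged)))
  }
  ct <- cor.test(merged$median_os_months, merged$n_up, method = "pearson")
  tibble::tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(merged))
}

#' Per-cancer counts of upregulated genes from a DE map
#'
#' @param de An `aars_de_map`.
#' @return Tibble with `cancer` and `n_up`, in map column order.
#' @export
de_up_counts_by_cancer <- function(de) {
  de$results |>
    dplyr::group_by(cancer = factor(.data$cancer, levels = de$cancer_order)) |>
    dplyr::summarise(n_up = sum(.data$call == "up"), .groups = "drop") |>
    dplyr::mutate(cancer = as.character(.data$cancer))
}
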