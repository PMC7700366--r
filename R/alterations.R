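#' Classify one sample's alteration state for a gene
#'
#' Applies the two-level treatment of thresholded copy-number calls: only the
#' high-level calls count as discrete alterations (+2 amplification, -2 deep
#' deletion); shallow deletion (-1), diploid (0) and low-level gain (+1) do
#' not. Mutations and fusions arrive as separate flags. A sample carrying two
#' or more distinct alteration classes is classified `"multiple"`.
#'
#' @param cnv_call Integer call in -2..+2.
#' @param has_mutation,has_fusion Logical flags for the discrete events.
#' @return One of `"amplification"`, `"deep_deletion"`, `"mutation"`,
#'   `"fusion"`, `"multiple"`, or `"none"`.
#' @export
classify_sample <- function(cnv_call, has_mutation = FALSE,
                            has_fusion = FALSE) {
  if (!cnv_call %in% -2:2) {
    abort(paste0("cnv_call must be in -2..2, got ", cnv_call))
  }
  classes <- c(
    if (cnv_call == 2L) "amplification",
    if (cnv_call == -2L) "deep_deletion",
    if (isTRUE(has_mutation)) "mutation",
    if (isTRUE(has_fusion)) "fusion"
  )
  if (length(classes) == 0) return("none")
  if (length(classes) > 1) return("multiple")
  classes
}

alteration_categories <- c("mutation", "fusion", "amplification",
                           "deep_deletion", "multiple")

#' Per-gene alteration frequency for one cancer
#'
#' For each gene, counts profiled tumor samples falling in each alteration
#' category (each sample counted once; samples with two or more distinct
#' event classes counted under `multiple`) and reports the alteration
#' frequency: the fraction of profiled samples with any such event. Fusions
#' are taken from the mutation table's `consequence == "fusion"` rows; all
#' other consequence classes count as mutations.
#'
#' @param cnv A CNV-call tibble (column `gene`, then one column per sample).
#' @param muts A mutation table (`sample_id`, `gene_symbol`,
#'   `protein_position`, `consequence`).
#' @param cancer Cancer abbreviation recorded in the output.
#' @return A tibble with one row per gene: per-category counts, `n_profiled`
#'   and `alteration_frequency`, plus an aggregate `"<panel>"` row giving the
#'   fraction of samples with any alteration in any panel gene.
#' @export
alteration_frequency <- function(cnv, muts, cancer) {
  mat <- gene_tbl_to_mat(cnv)
  if (ncol(mat) == 0) abort("zero profiled samples")
  check_calls(mat)
  samples <- colnames(mat)
  genes <- rownames(mat)

  mut_tbl <- dplyr::filter(muts, .data$consequence != "fusion")
  fus_tbl <- dplyr::filter(muts, .data$consequence == "fusion")
  has_mut <- event_flags(mut_tbl, genes, samples)
  has_fus <- event_flags(fus_tbl, genes, samples)

  amp <- mat == 2L
  del <- mat == -2L
  n_classes <- amp + del + has_mut + has_fus
  category <- function(class_mat) n_classes == 1L & class_mat
  multiple <- n_classes >= 2L
  altered_any <- n_classes >= 1L

  per_gene <- tibble::tibble(
    gene = genes,
    cancer = cancer,
    mutation = unname(rowSums(category(has_mut))),
    fusion = unname(rowSums(category(has_fus))),
    amplification = unname(rowSums(category(amp))),
    deep_deletion = unname(rowSums(category(del))),
    multiple = unname(rowSums(multiple)),
    n_profiled = length(samples)
  )
  per_gene$alteration_frequency <-
    rowSums(per_gene[alteration_categories]) / per_gene$n_profiled

  aggregate <- tibble::tibble(
    gene = "<panel>", cancer = cancer,
    mutation = NA_real_, fusion = NA_real_, amplification = NA_real_,
    deep_deletion = NA_real_, multiple = NA_real_,
    n_profiled = length(samples),
    alteration_frequency = mean(colSums(altered_any) > 0)
  )
  dplyr::bind_rows(per_gene, aggregate)
}

event_flags <- function(tbl, genes, samples) {
  flags <- matrix(FALSE, nrow = length(genes), ncol = length(samples),
                  dimnames = list(genes, samples))
  tbl <- dplyr::filter(tbl, .data$gene_symbol %in% genes,
                       .data$sample_id %in% samples)
  if (nrow(tbl) > 0) {
    flags[cbind(match(tbl$gene_symbol, genes),
                match(tbl$sample_id, samples))] <- TRUE
  }
  flags
}

check_calls <- function(mat) {
  if (!all(mat %in% -2:2)) {
    abort("CNV calls must all be in {-2, -1, 0, +1, +2}")
  }
  invisible(mat)
}

#' Mean thresholded copy-number score of a gene
#'
#' The arithmetic mean of a gene's calls over all profiled samples. Unlike
#' the discrete alteration categories, this average includes the low-level
#' calls (shallow deletion and gain), so it summarizes the overall degree of
#' amplification or deletion on a -2..+2 scale.
#'
#' @param cnv A CNV-call tibble (column `gene`, then sample columns).
#' @param gene Gene symbol.
#' @return A single numeric in \[-2, 2\].
#' @export
mean_gistic <- function(cnv, gene) {
  mat <- gene_tbl_to_mat(cnv)
  if (!gene %in% rownames(mat)) {
    abort(paste0("gene not present in CNV matrix: ", gene))
  }
  if (ncol(mat) == 0) abort("zero profiled samples")
  check_calls(mat)
  mean(mat[gene, ])
}

#' Gene-by-cancer mean copy-number score heatmap
#'
#' Rows follow the registry order; columns follow the canonical ordering of
#' cancers by ascending median overall survival.
#'
#' @param cohort An `aars_cohort` (only the `cnv` tables are used).
#' @param registry Gene registry tibble; its `symbol` order fixes row order.
#' @param cancers Cancer-table tibble (subset to the cohort's cancers).
#' @return A wide tibble: `gene` column plus one ordered column per cancer,
#'   cells holding [mean_gistic()] values.
#' @export
gistic_heatmap <- function(cohort, registry, cancers) {
  cancers <- dplyr::filter(cancers, .data$abbreviation %in% cohort$cancers)
  ordered <- sort_cancers_by_os(cancers)$abbreviation
  cols <- lapply(ordered, function(cancer) {
    mat <- gene_tbl_to_mat(cohort$data[[cancer]]$cnv)
    check_calls(mat)
    absent <- setdiff(registry$symbol, rownames(mat))
    if (length(absent) > 0) {
      abort(paste0("gene(s) missing from CNV matrix of ", cancer, ": ",
                   paste(absent, collapse = ", ")))
    }
    unname(rowMeans(mat[registry$symbol, , drop = FALSE]))
  })
  names(cols) <- ordered
  dplyr::bind_cols(tibble::tibble(gene = registry$symbol),
                   tibble::as_tibble(cols))
}

#' Tally mutation positions along a protein and flag hotspots
#'
#' Counts mutations at each residue of one gene's protein product (rows with
#' a missing position, e.g. fusions, are ignored) and reports hotspot
#' residues whose count reaches `hotspot_min`, the smallest pile-up that
#' stands out against a background of mutations spread across the protein.
#'
#' @param muts Mutation table.
#' @param gene Gene symbol to tally.
#' @param protein_length Protein length in residues; must cover every
#'   observed position.
#' @param hotspot_min Minimum per-residue count to call a hotspot (default 3).
#' @return A list with `counts` (a tibble `residue`, `count` of length
#'   `protein_length`) and `hotspots` (a tibble `residue`, `count`, count
#'   descending, residue ascending within ties).
#' @export
mutation_position_tally <- function(muts, gene, protein_length,
                                    hotspot_min = 3L) {
  stopifnot(protein_length >= 1)
  pos <- dplyr::filter(muts, .data$gene_symbol == gene,
                       !is.na(.data$protein_position))$protein_position
  if (length(pos) > 0 && max(pos) > protein_length) {
    abort(paste0("observed protein position ", max(pos),
                 " exceeds protein_length ", protein_length))
  }
  if (length(pos) > 0 && min(pos) < 1) abort("protein positions must be >= 1")
  counts <- tabulate(pos, nbins = protein_length)
  hot <- which(counts >= hotspot_min)
  hotspots <- tibble::tibble(residue = hot, count = counts[hot])
  hotspots <- dplyr::arrange(hotspots, dplyr::desc(.data$count),
                             .data$residue)
  list(counts = tibble::tibble(residue = seq_len(protein_length),
                               count = counts),
       hotspots = hotspots)
}
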