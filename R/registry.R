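#' Load the aaRS/AIMP/reference gene panel
#'
#' Reads a tab-separated gene registry with columns `symbol`, `locality`
#' (`cytoplasmic`, `mitochondrial` or `dual`), `family` (`aaRS`, `AIMP` or
#' `reference`) and optionally `msc_member` (logical, membership in the
#' multi-synthetase complex). The packaged default covers the 37 human aaRS
#' genes (20 cytoplasmic and 19 mitochondrial enzymes, with the dual-localized
#' GARS1 and KARS1 counted under both compartments), the three AIMPs (AIMP1,
#' AIMP2, EEF1E1) and three cancer reference genes (RB1, MYC, EIF4E).
#'
#' @param path Path to a registry TSV. Defaults to the packaged panel.
#' @return A tibble with one row per gene, file order preserved, columns
#'   `symbol`, `locality`, `family`, `msc_member`.
#' @examples
#' reg <- load_gene_registry()
#' nrow(reg)                      # 43
#' registry_counts(reg)
#' @export
load_gene_registry <- function(path = aarscan_extdata("aars_gene_registry.tsv")) {
  if (!file.exists(path)) {
    abort(paste0("registry file not found: ", path))
  }
  reg <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(reg) == 0) {
    warn("gene registry file is empty")
    return(tibble::tibble(symbol = character(), locality = character(),
                          family = character(), msc_member = logical()))
  }
  needed <- c("symbol", "locality", "family")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"msc_member" %in% names(reg)) reg$msc_member <- FALSE
  dup <- unique(reg$symbol[duplicated(reg$symbol)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene symbol(s) in registry: ",
                 paste(dup, collapse = ", ")))
  }
  bad_loc <- setdiff(unique(reg$locality),
                     c("cytoplasmic", "mitochondrial", "dual"))
  if (length(bad_loc) > 0) {
    abort(paste0("unknown locality token(s): ", paste(bad_loc, collapse = ", ")))
  }
  bad_fam <- setdiff(unique(reg$family), c("aaRS", "AIMP", "reference"))
  if (length(bad_fam) > 0) {
    abort(paste0("unknown family token(s): ", paste(bad_fam, collapse = ", ")))
  }
  dplyr::select(reg, "symbol", "locality", "family", "msc_member")
}

#' Panel composition counts
#'
#' Locality counts are computed over the aaRS family only, with dual-localized
#' genes counted under both compartments.
#'
#' @param registry A registry tibble from [load_gene_registry()].
#' @return A one-row tibble with counts: total genes, unique aaRS symbols,
#'   cytoplasmic and mitochondrial aaRS counts (dual counted in both),
#'   dual-localized genes, AIMPs and reference genes.
#' @export
registry_counts <- function(registry) {
  aars <- dplyr::filter(registry, .data$family == "aaRS")
  tibble::tibble(
    n_total = nrow(registry),
    n_aars = nrow(aars),
    n_cytoplasmic = sum(aars$locality %in% c("cytoplasmic", "dual")),
    n_mitochondrial = sum(aars$locality %in% c("mitochondrial", "dual")),
    n_dual = sum(aars$locality == "dual"),
    n_aimp = sum(registry$family == "AIMP"),
    n_reference = sum(registry$family == "reference")
  )
}

#' Load the cancer-type catalog
#'
#' Reads a TSV with columns `abbreviation`, `full_name` and
#' `median_os_months` (median overall-survival time to event, months). The
#' packaged default transcribes the 33 TCGA cancer types.
#'
#' @param path Path to a cancer-table TSV. Defaults to the packaged catalog.
#' @return A tibble, one row per cancer type, file order preserved.
#' @export
load_cancer_table <- function(path = aarscan_extdata("tcga_cancer_types.tsv")) {
  if (!file.exists(path)) {
    abort(paste0("cancer table not found: ", path))
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tab) == 0) {
    warn("cancer table file is empty")
    return(tibble::tibble(abbreviation = character(), full_name = character(),
                          median_os_months = double()))
  }
  needed <- c("abbreviation", "full_name", "median_os_months")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("cancer table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(tab$abbreviation[duplicated(tab$abbreviation)])
  if (length(dup) > 0) {
    abort(paste0("duplicate cancer abbreviation(s): ",
                 paste(dup, collapse = ", ")))
  }
  if (!is.numeric(tab$median_os_months) || anyNA(tab$median_os_months)) {
    abort("median_os_months must be numeric and complete")
  }
  if (any(tab$median_os_months <= 0)) {
    abort("median_os_months must be positive")
  }
  dplyr::select(tab, "abbreviation", "full_name", "median_os_months")
}

#' Order cancer types by median overall survival
#'
#' Ascending by median overall-survival months, ties broken alphabetically by
#' abbreviation. This ordering (most aggressive cancer first) is the canonical
#' column order of every gene-by-cancer map the pipeline emits.
#'
#' @param cancers A cancer-table tibble from [load_cancer_table()].
#' @return The same tibble, reordered.
#' @export
sort_cancers_by_os <- function(cancers) {
  dplyr::arrange(cancers, .data$median_os_months, .data$abbreviation)
}

aarscan_extdata <- function(file) {
  system.file("extdata", file, package = "aarscan", mustWork = FALSE)
}
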