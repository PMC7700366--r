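#' Build a validated synthetic-cohort configuration
#'
#' The generator emulates the statistical structure of a TCGA-like pan-cancer
#' study: per-cancer tumor cohorts with GISTIC-style thresholded copy-number
#' calls, a minimal MAF-like mutation table, log-normal expression for tumor
#' and normal cohorts, and exponential overall-survival times whose hazard is
#' tied to the median split of one designated driver gene per cancer.
#'
#' Each gene carries one of three archetypes. `oncogene_like` genes are
#' amplification-prone, upshifted in tumors and hazard-increasing when highly
#' expressed; `suppressor_like` genes mirror that (deletion-prone, downshifted,
#' protective); `neutral` genes have symmetric copy-number noise and no
#' planted effect.
#'
#' @param cancers Character vector of cancer-type abbreviations.
#' @param n_tumor,n_normal Samples per cancer (each at least 4).
#' @param genes Character vector of gene symbols.
#' @param archetype Named character vector mapping every gene to
#'   `"oncogene_like"`, `"suppressor_like"` or `"neutral"`.
#' @param cnv_probs Named list (one entry per archetype) of length-5
#'   probability vectors over the thresholded calls (-2, -1, 0, +1, +2);
#'   each must sum to 1.
#' @param expr_base_log2 Mean of normal-cohort expression on the
#'   log2(TPM + 1) scale.
#' @param expr_sd_log2 Standard deviation on the same scale.
#' @param expr_shift_log2 Named numeric (per archetype): additive tumor shift
#'   on the log2 scale. Positive for `oncogene_like`, negative for
#'   `suppressor_like`, zero for `neutral`.
#' @param mutation_rate Per-sample, per-gene probability of a discrete
#'   mutation event.
#' @param baseline_hazard Exponential baseline hazard, events per month.
#' @param log_hr_per_group Named numeric (per archetype): log hazard of the
#'   high-expression group relative to the low group for a driver gene of
#'   that archetype. Sign constraints as for `expr_shift_log2`.
#' @param censor_horizon_months Administrative censoring time, months.
#' @param driver_map Named character vector (cancer -> gene symbol) selecting
#'   the gene whose tumor-expression median split drives survival in that
#'   cancer. Defaults to a round-robin assignment of the non-neutral genes
#'   (all genes if none are planted).
#' @param seed Integer seed; one RNG stream is used for the whole cohort.
#' @return A validated `aars_synth_config` list.
#' @seealso [default_config()], [generate_cohort()]
#' @export
synthetic_config <- function(cancers, n_tumor, n_normal, genes, archetype,
                             cnv_probs = default_cnv_probs(),
                             expr_base_log2 = 5, expr_sd_log2 = 1,
                             expr_shift_log2 = c(oncogene_like = 1,
                                                 suppressor_like = -1,
                                                 neutral = 0),
                             mutation_rate = 0.02,
                             baseline_hazard = 0.03,
                             log_hr_per_group = c(oncogene_like = 0.7,
                                                  suppressor_like = -0.7,
                                                  neutral = 0),
                             censor_horizon_months = 60,
                             driver_map = NULL,
                             seed = 1L) {
  archetypes <- c("oncogene_like", "suppressor_like", "neutral")
  if (n_tumor < 4 || n_normal < 4) {
    abort("n_tumor and n_normal must each be at least 4")
  }
  if (anyDuplicated(genes)) abort("gene symbols must be unique")
  if (anyDuplicated(cancers)) abort("cancer abbreviations must be unique")
  unknown <- setdiff(names(archetype), genes)
  if (length(unknown) > 0) {
    abort(paste0("archetype map names unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  missing_genes <- setdiff(genes, names(archetype))
  if (length(missing_genes) > 0) {
    abort(paste0("archetype missing for gene(s): ",
                 paste(missing_genes, collapse = ", ")))
  }
  bad_arch <- setdiff(unique(archetype), archetypes)
  if (length(bad_arch) > 0) {
    abort(paste0("unknown archetype token(s): ",
                 paste(bad_arch, collapse = ", ")))
  }
  for (nm in archetypes) {
    p <- cnv_probs[[nm]]
    if (is.null(p) || length(p) != 5 || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      abort(paste0("cnv_probs$", nm,
                   " must be 5 non-negative probabilities summing to 1"))
    }
  }
  stopifnot(expr_sd_log2 > 0, baseline_hazard > 0, censor_horizon_months > 0,
            mutation_rate >= 0, mutation_rate <= 1)
  if (!(expr_shift_log2[["oncogene_like"]] > 0 &&
        log_hr_per_group[["oncogene_like"]] > 0 &&
        expr_shift_log2[["suppressor_like"]] < 0 &&
        log_hr_per_group[["suppressor_like"]] < 0 &&
        expr_shift_log2[["neutral"]] == 0 &&
        log_hr_per_group[["neutral"]] == 0)) {
    abort(paste0("archetype effect signs must be: oncogene_like positive, ",
                 "suppressor_like negative, neutral zero"))
  }
  if (is.null(driver_map)) {
    planted <- names(archetype)[archetype != "neutral"]
    pool <- if (length(planted) > 0) planted else genes
    driver_map <- setNames(
      rep_len(pool, length(cancers)), cancers)
  }
  if (!setequal(names(driver_map), cancers) ||
      !all(driver_map %in% genes)) {
    abort("driver_map must assign one panel gene to every cancer")
  }
  structure(list(
    cancers = as.character(cancers),
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    genes = as.character(genes),
    archetype = archetype[genes],
    cnv_probs = cnv_probs[archetypes],
    expr_base_log2 = expr_base_log2, expr_sd_log2 = expr_sd_log2,
    expr_shift_log2 = expr_shift_log2[archetypes],
    mutation_rate = mutation_rate,
    baseline_hazard = baseline_hazard,
    log_hr_per_group = log_hr_per_group[archetypes],
    censor_horizon_months = censor_horizon_months,
    driver_map = driver_map[as.character(cancers)],
    seed = as.integer(seed)
  ), class = "aars_synth_config")
}

#' Archetype-specific copy-number call probabilities
#'
#' Probabilities over the thresholded calls (-2, -1, 0, +1, +2).
#' Oncogene-like genes are gain/amplification-prone, suppressor-like genes
#' mirror that towards deletion, neutral genes are symmetric with modest
#' shallow events.
#'
#' @return Named list of three length-5 probability vectors.
#' @export
default_cnv_probs <- function() {
  list(
    oncogene_like   = c(0.01, 0.04, 0.60, 0.25, 0.10),
    suppressor_like = c(0.10, 0.25, 0.60, 0.04, 0.01),
    neutral         = c(0.01, 0.09, 0.80, 0.09, 0.01)
  )
}

# Planted archetypes for the paper_like scenario: genes whose pan-cancer
# profiles resemble an oncogene (amplification / upregulation / unfavorable
# survival) or a tumor suppressor in the aaRS panel.
paper_like_oncogenes <- c("GARS1", "TARS1", "AIMP2", "DARS2", "YARS2")
paper_like_suppressors <- c("NARS1", "SARS1", "QARS1", "LARS2", "RARS2")

#' Canned simulation scenarios
#'
#' `"small"` is a fast null scenario: the 4 shortest-survival cancer types,
#' the first 40 panel genes, 60 tumor / 30 normal samples per cancer, and all
#' genes neutral (no planted effects) — the configuration used for
#' false-positive-rate calibration. `"paper_like"` uses the 10
#' shortest-survival cancer types, the full 43-gene panel, 200 tumor / 100
#' normal samples, 5 planted oncogene-like and 5 suppressor-like genes, each
#' serving as the survival driver of exactly one cancer, with a fixed
#' documented seed.
#'
#' @param scenario `"small"` or `"paper_like"`.
#' @param seed Optional seed override; the defaults are 101 (`small`) and
#'   20201122 (`paper_like`).
#' @return An `aars_synth_config`.
#' @export
default_config <- function(scenario = c("small", "paper_like"), seed = NULL) {
  if (!is.character(scenario) || !scenario[1] %in% c("small", "paper_like")) {
    abort(paste0("unknown scenario: ", scenario[1]))
  }
  scenario <- match.arg(scenario)
  registry <- load_gene_registry()
  cancers <- sort_cancers_by_os(load_cancer_table())$abbreviation
  if (scenario == "small") {
    genes <- registry$symbol[seq_len(40)]
    synthetic_config(
      cancers = cancers[1:4], n_tumor = 60, n_normal = 30,
      genes = genes,
      archetype = setNames(rep("neutral", length(genes)), genes),
      seed = seed %||% 101L
    )
  } else {
    genes <- registry$symbol
    arch <- setNames(rep("neutral", length(genes)), genes)
    arch[paper_like_oncogenes] <- "oncogene_like"
    arch[paper_like_suppressors] <- "suppressor_like"
    ten <- cancers[1:10]
    drivers <- setNames(
      as.vector(rbind(paper_like_oncogenes, paper_like_suppressors)), ten)
    synthetic_config(
      cancers = ten, n_tumor = 200, n_normal = 100,
      genes = genes, archetype = arch, driver_map = drivers,
      seed = seed %||% 20201122L
    )
  }
}

#' Generate a synthetic per-cancer cohort
#'
#' Draws, for every cancer in the configuration: a gene-by-sample matrix of
#' thresholded copy-number calls (per-gene archetype probabilities), a
#' MAF-minimal mutation table, tumor and normal expression matrices
#' (log-normal on the log2(TPM + 1) scale, tumors shifted by the archetype
#' effect, back-transformed and floored at 0), and an overall-survival table.
#' Survival times are exponential with hazard
#' `baseline_hazard * exp(log_hr * high)`, where `high` marks tumor samples in
#' the upper half of the designated driver gene's expression and `log_hr` is
#' the driver archetype's effect; times are administratively censored at the
#' horizon. A single RNG stream seeded once makes the cohort fully
#' reproducible.
#'
#' @param config An `aars_synth_config` from [synthetic_config()] or
#'   [default_config()].
#' @return An `aars_cohort`: list with elements `config`, `cancers`, and
#'   `data` (per cancer: `cnv`, `mutations`, `expr_tumor`, `expr_normal`,
#'   `survival`, `driver`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "aars_synth_config")) {
    abort("config must be built with synthetic_config() or default_config()")
  }
  set.seed(config$seed)
  calls <- c(-2L, -1L, 0L, 1L, 2L)
  consequences <- c("missense", "nonsense", "frameshift", "fusion", "other")
  cons_probs <- c(0.70, 0.10, 0.10, 0.05, 0.05)
  genes <- config$genes
  arch <- config$archetype
  data <- lapply(config$cancers, function(cancer) {
    tumor_ids <- sprintf("%s-T%04d", cancer, seq_len(config$n_tumor))
    normal_ids <- sprintf("%s-N%04d", cancer, seq_len(config$n_normal))

    cnv <- vapply(genes, function(g) {
      sample(calls, config$n_tumor, replace = TRUE,
             prob = config$cnv_probs[[arch[[g]]]])
    }, integer(config$n_tumor))
    cnv <- t(cnv)  # gene x sample
    colnames(cnv) <- tumor_ids

    mut_hits <- which(
      matrix(runif(length(genes) * config$n_tumor) < config$mutation_rate,
             nrow = length(genes)), arr.ind = TRUE)
    n_mut <- nrow(mut_hits)
    cons <- if (n_mut > 0) {
      sample(consequences, n_mut, replace = TRUE, prob = cons_probs)
    } else character()
    mutations <- tibble::tibble(
      sample_id = tumor_ids[mut_hits[, 2]],
      gene_symbol = genes[mut_hits[, 1]],
      protein_position = ifelse(cons == "fusion", NA_integer_,
                                sample(600L, n_mut, replace = TRUE)),
      consequence = cons
    )

    shift <- unname(config$expr_shift_log2[arch])
    z_normal <- matrix(
      rnorm(length(genes) * config$n_normal, mean = config$expr_base_log2,
            sd = config$expr_sd_log2),
      nrow = length(genes), dimnames = list(genes, normal_ids))
    z_tumor <- matrix(
      rnorm(length(genes) * config$n_tumor, mean = config$expr_base_log2,
            sd = config$expr_sd_log2),
      nrow = length(genes), dimnames = list(genes, tumor_ids)) + shift
    expr_normal <- pmax(2^z_normal - 1, 0)
    expr_tumor <- pmax(2^z_tumor - 1, 0)

    driver <- config$driver_map[[cancer]]
    drv_expr <- expr_tumor[driver, ]
    high <- drv_expr > median(drv_expr)
    hazard <- config$baseline_hazard *
      exp(config$log_hr_per_group[[arch[[driver]]]] * high)
    t_event <- rexp(config$n_tumor, rate = hazard)
    observed <- t_event <= config$censor_horizon_months
    survival <- tibble::tibble(
      sample_id = tumor_ids,
      time_months = pmin(t_event, config$censor_horizon_months),
      event = observed
    )

    list(
      cnv = mat_to_gene_tbl(cnv),
      mutations = mutations,
      expr_tumor = mat_to_gene_tbl(expr_tumor),
      expr_normal = mat_to_gene_tbl(expr_normal),
      survival = survival,
      driver = driver
    )
  })
  names(data) <- config$cancers
  structure(list(config = config, cancers = config$cancers, data = data),
            class = "aars_cohort")
}

#' @export
print.aars_cohort <- function(x, ...) {
  cat("<aars_cohort> ", length(x$cancers), " cancer type(s), ",
      length(x$config$genes), " genes, ",
      x$config$n_tumor, " tumor / ", x$config$n_normal,
      " normal samples per cancer (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a cohort to per-cancer TSV files
#'
#' Emits, per cancer, `<CANCER>.cnv.tsv`, `<CANCER>.mutations.tsv`,
#' `<CANCER>.tumor.tsv`, `<CANCER>.normal.tsv` and `<CANCER>.survival.tsv`
#' (survival events encoded 0/1), plus `drivers.tsv` recording each cancer's
#' designated survival driver gene.
#'
#' @param cohort An `aars_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- unlist(lapply(cohort$cancers, function(cancer) {
    d <- cohort$data[[cancer]]
    p <- file.path(dir, paste0(cancer, c(".cnv.tsv", ".mutations.tsv",
                                         ".tumor.tsv", ".normal.tsv",
                                         ".survival.tsv")))
    readr::write_tsv(d$cnv, p[1], progress = FALSE)
    readr::write_tsv(d$mutations, p[2], progress = FALSE)
    readr::write_tsv(d$expr_tumor, p[3], progress = FALSE)
    readr::write_tsv(d$expr_normal, p[4], progress = FALSE)
    surv <- dplyr::mutate(d$survival, event = as.integer(.data$event))
    readr::write_tsv(surv, p[5], progress = FALSE)
    p
  }))
  drv <- tibble::tibble(cancer = cohort$cancers,
                        driver = vapply(cohort$data, `[[`, "", "driver"))
  drv_path <- file.path(dir, "drivers.tsv")
  readr::write_tsv(drv, drv_path, progress = FALSE)
  invisible(c(paths, drv_path))
}

#' Read a cohort from per-cancer TSV files
#'
#' Counterpart of [write_cohort()] for ingest-mode analysis of user-supplied
#' data laid out in the same file convention. Missing mutation or survival
#' files for a cancer are tolerated (empty tables substituted, for the former,
#' `NULL` for the latter); missing expression or CNV files raise an error.
#'
#' @param dir Directory holding the per-cancer TSVs.
#' @param cancers Cancer abbreviations to load.
#' @return An `aars_cohort` without a generating config (`config = NULL`).
#' @export
read_cohort <- function(dir, cancers) {
  data <- lapply(cancers, function(cancer) {
    path <- function(suffix) file.path(dir, paste0(cancer, suffix))
    for (suffix in c(".cnv.tsv", ".tumor.tsv", ".normal.tsv")) {
      if (!file.exists(path(suffix))) {
        abort(paste0("missing required file for ", cancer, ": ", path(suffix)))
      }
    }
    mutations <- if (file.exists(path(".mutations.tsv"))) {
      readr::read_tsv(path(".mutations.tsv"), show_col_types = FALSE,
                      progress = FALSE)
    } else {
      tibble::tibble(sample_id = character(), gene_symbol = character(),
                     protein_position = integer(), consequence = character())
    }
    survival <- if (file.exists(path(".survival.tsv"))) {
      dplyr::mutate(
        readr::read_tsv(path(".survival.tsv"), show_col_types = FALSE,
                        progress = FALSE),
        event = as.logical(.data$event))
    } else {
      NULL
    }
    list(
      cnv = readr::read_tsv(path(".cnv.tsv"), show_col_types = FALSE,
                            progress = FALSE),
      mutations = mutations,
      expr_tumor = readr::read_tsv(path(".tumor.tsv"), show_col_types = FALSE,
                                   progress = FALSE),
      expr_normal = readr::read_tsv(path(".normal.tsv"),
                                    show_col_types = FALSE, progress = FALSE),
      survival = survival,
      driver = NA_character_
    )
  })
  names(data) <- cancers
  structure(list(config = NULL, cancers = cancers, data = data),
            class = "aars_cohort")
}

# gene-by-sample matrix <-> tibble with leading `gene` column
mat_to_gene_tbl <- function(mat) {
  tibble::as_tibble(mat, rownames = "gene")
}

gene_tbl_to_mat <- function(tbl) {
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(mat) <- tbl$gene
  mat
}
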