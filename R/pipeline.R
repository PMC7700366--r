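#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort from a scenario or an
#'   explicit [synthetic_config()]) or `"ingest"` (read per-cancer TSVs laid
#'   out as written by [write_cohort()]).
#' @param out_dir Output directory for all maps, tables and the manifest.
#' @param scenario Scenario name for synthetic mode (see [default_config()]);
#'   ignored when `synth_config` is supplied.
#' @param synth_config Optional explicit `aars_synth_config`.
#' @param input_dir,input_cancers Ingest mode: directory of per-cancer TSVs
#'   and the cancer abbreviations to load.
#' @param fc_threshold,q_de,q_surv,hotspot_min Analysis thresholds: linear
#'   fold-change gate and FDR gates for the differential-expression and
#'   survival maps, and the minimum per-residue count for mutation hotspots.
#' @param seed Seed for synthetic generation (overrides the scenario
#'   default when supplied).
#' @return A validated `aars_run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "ingest"), out_dir,
                       scenario = "small", synth_config = NULL,
                       input_dir = NULL, input_cancers = NULL,
                       fc_threshold = 1.5, q_de = 0.05, q_surv = 0.05,
                       hotspot_min = 3L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(fc_threshold > 0, hotspot_min >= 1)
  if (q_de <= 0 || q_de >= 1 || q_surv <= 0 || q_surv >= 1) {
    abort("q thresholds must lie in (0, 1)")
  }
  if (mode == "ingest" && (is.null(input_dir) || is.null(input_cancers))) {
    abort("ingest mode needs input_dir and input_cancers")
  }
  structure(list(mode = mode, out_dir = out_dir, scenario = scenario,
                 synth_config = synth_config, input_dir = input_dir,
                 input_cancers = input_cancers, fc_threshold = fc_threshold,
                 q_de = q_de, q_surv = q_surv,
                 hotspot_min = as.integer(hotspot_min), seed = seed),
            class = "aars_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts the same fields as [run_config()].
#'
#' @param path YAML file path.
#' @return An `aars_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Generates or ingests a per-cancer cohort, then runs the four analysis
#' stages in order — genomic alterations (mean copy-number heatmap,
#' alteration frequencies, mutation hotspot tallies), tumor-vs-normal
#' differential expression, expression-stratified survival mapping, and the
#' three-level score integration — and writes every map plus a
#' machine-readable manifest to `config$out_dir`. All gene-by-cancer outputs
#' share the canonical cancer ordering by ascending median overall survival.
#'
#' Output files: `gistic_heatmap.tsv`, `alteration_frequency.tsv`,
#' `mutation_hotspots.tsv`, `de_map.tsv` (calls encoded +1/-1/0) with
#' `de_totals.tsv`, `survival_map.tsv` with `survival_totals.tsv`,
#' `integration.tsv`, `correlations.tsv` and `manifest.json`.
#'
#' @param config An `aars_run_config`.
#' @return An `aars_run_report`: list with `paths` (named output files),
#'   `summary` (per-stage glance rows), `ranking`, `warnings`, and the
#'   effective seed.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "aars_run_config")) {
    abort("config must be built with run_config() or read_run_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  warnings_seen <- character()
  out <- function(file) file.path(config$out_dir, file)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stage <- function(name, expr) {
    tryCatch(collect(expr), error = function(e) {
      for (p in paths) if (file.exists(p)) {
        file.rename(p, paste0(p, ".partial"))
      }
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  cohort <- stage("cohort", {
    if (config$mode == "synthetic") {
      sc <- config$synth_config %||%
        default_config(config$scenario, seed = config$seed)
      generate_cohort(sc)
    } else {
      read_cohort(config$input_dir, config$input_cancers)
    }
  })
  seed_used <- if (config$mode == "synthetic") cohort$config$seed else NA

  registry <- load_gene_registry()
  cohort_genes <- cohort$data[[1]]$cnv$gene
  registry <- dplyr::filter(registry, .data$symbol %in% cohort_genes)
  cancers <- dplyr::filter(load_cancer_table(),
                           .data$abbreviation %in% cohort$cancers)

  heatmap <- stage("alterations", {
    hm <- gistic_heatmap(cohort, registry, cancers)
    readr::write_tsv(hm, out("gistic_heatmap.tsv"), progress = FALSE)
    paths["gistic_heatmap"] <- out("gistic_heatmap.tsv")
    freq <- purrr::map_dfr(cohort$cancers, function(cancer) {
      alteration_frequency(cohort$data[[cancer]]$cnv,
                           cohort$data[[cancer]]$mutations, cancer)
    })
    readr::write_tsv(freq, out("alteration_frequency.tsv"), progress = FALSE)
    paths["alteration_frequency"] <- out("alteration_frequency.tsv")
    muts <- purrr::map_dfr(cohort$cancers,
                           function(cancer) cohort$data[[cancer]]$mutations)
    hot <- purrr::map_dfr(registry$symbol, function(g) {
      pos <- muts$protein_position[muts$gene_symbol == g]
      len <- if (all(is.na(pos))) 1L else max(pos, na.rm = TRUE)
      tal <- mutation_position_tally(muts, g, len, config$hotspot_min)
      if (nrow(tal$hotspots) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(gene = g), tal$hotspots)
    })
    if (nrow(hot) == 0) {
      hot <- tibble::tibble(gene = character(), residue = integer(),
                            count = integer())
    }
    readr::write_tsv(hot, out("mutation_hotspots.tsv"), progress = FALSE)
    paths["mutation_hotspots"] <- out("mutation_hotspots.tsv")
    hm
  })

  de <- stage("diffexpr", {
    de <- de_map(cohort, registry, cancers,
                 fc_threshold = config$fc_threshold,
                 q_threshold = config$q_de)
    encoded <- de$results |>
      dplyr::mutate(code = c(up = 1L, down = -1L, ns = 0L)[.data$call]) |>
      dplyr::select("gene", "cancer", "code") |>
      tidyr::pivot_wider(names_from = "cancer", values_from = "code")
    readr::write_tsv(encoded, out("de_map.tsv"), progress = FALSE)
    readr::write_tsv(de$totals, out("de_totals.tsv"), progress = FALSE)
    paths["de_map"] <- out("de_map.tsv")
    paths["de_totals"] <- out("de_totals.tsv")
    de
  })

  surv <- stage("survival", {
    sv <- survival_map(cohort, registry, cancers, q_threshold = config$q_surv)
    readr::write_tsv(
      dplyr::select(sv$results, "gene", "cancer", "hazard_ratio",
                    "logrank_p", "q_value", "direction"),
      out("survival_map.tsv"), progress = FALSE)
    readr::write_tsv(sv$totals, out("survival_totals.tsv"), progress = FALSE)
    paths["survival_map"] <- out("survival_map.tsv")
    paths["survival_totals"] <- out("survival_totals.tsv")
    sv
  })

  ranking <- stage("integration", {
    scores <- integration_scores(heatmap, de, surv)
    rk <- composite_rank(scores)
    readr::write_tsv(rk$scores, out("integration.tsv"), progress = FALSE)
    readr::write_tsv(cross_level_correlations(scores),
                     out("correlations.tsv"), progress = FALSE)
    paths["integration"] <- out("integration.tsv")
    paths["correlations"] <- out("correlations.tsv")
    rk
  })

  manifest <- list(
    pipeline = "aarscan",
    version = as.character(utils::packageVersion("aarscan")),
    mode = config$mode,
    scenario = if (config$mode == "synthetic") config$scenario else NULL,
    seed = seed_used,
    thresholds = list(fc_threshold = config$fc_threshold,
                      q_de = config$q_de, q_surv = config$q_surv,
                      hotspot_min = config$hotspot_min),
    cancers = cohort$cancers,
    n_genes = nrow(registry),
    warnings = warnings_seen,
    outputs = as.list(setNames(basename(paths), names(paths))),
    md5 = as.list(setNames(unname(tools::md5sum(paths)), names(paths)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  paths["manifest"] <- out("manifest.json")

  structure(list(paths = paths,
                 summary = list(de = glance(de), survival = glance(surv),
                                ranking = glance(ranking)),
                 ranking = ranking, warnings = warnings_seen,
                 seed = seed_used),
            class = "aars_run_report")
}

#' @export
print.aars_run_report <- function(x, ...) {
  cat("<aars_run_report> ", length(x$paths), " output file(s) in ",
      dirname(x$paths[[1]]), "\n", sep = "")
  if (length(x$warnings) > 0) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  print(x$ranking)
  invisible(x)
}
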