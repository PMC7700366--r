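test_that("sample classification follows the two-level call semantics", {
  expect_equal(classify_sample(2), "amplification")
  expect_equal(classify_sample(-2), "deep_deletion")
  expect_equal(classify_sample(0), "none")
  expect_equal(classify_sample(1), "none")
  expect_equal(classify_sample(-1), "none")
  expect_equal(classify_sample(0, has_mutation = TRUE), "mutation")
  expect_equal(classify_sample(1, has_fusion = TRUE), "fusion")
  expect_equal(classify_sample(-2, has_mutation = TRUE), "multiple")
  expect_equal(classify_sample(2, has_mutation = TRUE, has_fusion = TRUE),
               "multiple")
  expect_error(classify_sample(3), "-2..2")
})

test_that("alteration frequency counts each sample once in its category", {
  cnv <- gene_tbl("GENE", matrix(c(2L, 2L, 2L, rep(0L, 7)), nrow = 1))
  muts <- tibble::tibble(sample_id = c("s3", "s4"),
                         gene_symbol = "GENE",
                         protein_position = c(10L, 20L),
                         consequence = "missense")
  prof <- alteration_frequency(cnv, muts, "LAML")
  row <- prof[prof$gene == "GENE", ]
  expect_equal(row$amplification, 2)   # s1, s2 amplified only
  expect_equal(row$mutation, 1)        # s4 mutated only
  expect_equal(row$multiple, 1)        # s3 amplified + mutated
  expect_equal(row$fusion, 0)
  expect_equal(row$deep_deletion, 0)
  expect_equal(row$n_profiled, 10)
  expect_equal(row$alteration_frequency, 0.4)
  # category counts sum to the number of altered samples
  expect_equal(sum(row[c("mutation", "fusion", "amplification",
                         "deep_deletion", "multiple")]), 4)
})

test_that("unaltered cohorts have zero frequency and the panel aggregate dominates", {
  cnv <- gene_tbl(c("A", "B"), matrix(0L, nrow = 2, ncol = 6))
  muts <- tibble::tibble(sample_id = character(), gene_symbol = character(),
                         protein_position = integer(),
                         consequence = character())
  prof <- alteration_frequency(cnv, muts, "LAML")
  expect_true(all(prof$alteration_frequency == 0))

  set.seed(42)
  for (i in 1:5) {
    cnv <- gene_tbl(c("A", "B", "C"),
                    matrix(sample(-2:2, 30, replace = TRUE), nrow = 3))
    prof <- alteration_frequency(cnv, muts, "LAML")
    agg <- prof$alteration_frequency[prof$gene == "<panel>"]
    expect_gte(agg, max(prof$alteration_frequency[prof$gene != "<panel>"]))
  }
  expect_error(alteration_frequency(cnv[, 1, drop = FALSE], muts, "LAML"),
               "zero profiled")
})

test_that("alteration frequency is invariant under sample reordering", {
  set.seed(7)
  cnv <- gene_tbl(c("A", "B"), matrix(sample(-2:2, 20, replace = TRUE),
                                      nrow = 2))
  muts <- tibble::tibble(sample_id = c("s1", "s5"), gene_symbol = "A",
                         protein_position = c(5L, 9L),
                         consequence = c("missense", "fusion"))
  perm <- c(1, sample(2:11))  # keep gene column first
  prof1 <- alteration_frequency(cnv, muts, "LAML")
  prof2 <- alteration_frequency(cnv[, perm], muts, "LAML")
  expect_equal(prof1, prof2)
})

test_that("mean copy-number score is the plain arithmetic mean of calls", {
  cnv <- gene_tbl("G", matrix(c(2L, 2L, 0L, -1L, 1L), nrow = 1))
  expect_equal(mean_gistic(cnv, "G"), 0.8)
  cnv2 <- gene_tbl("G", matrix(rep(-2L, 4), nrow = 1))
  expect_equal(mean_gistic(cnv2, "G"), -2)
  expect_error(mean_gistic(cnv, "H"), "not present")
  bad <- gene_tbl("G", matrix(c(3L, 0L), nrow = 1))
  expect_error(mean_gistic(bad, "G"), "calls")
})

test_that("copy-number heatmap equals brute-force per-cell recomputation", {
  registry <- tibble::tibble(symbol = paste0("G", 1:5),
                             locality = "cytoplasmic", family = "aaRS",
                             msc_member = FALSE)
  cancers <- load_cancer_table()[1:5, ]
  set.seed(99)
  for (rep in 1:3) {
    mats <- lapply(cancers$abbreviation, function(cc) {
      gene_tbl(registry$symbol,
               matrix(sample(-2:2, 25, replace = TRUE), nrow = 5),
               prefix = cc)
    })
    names(mats) <- cancers$abbreviation
    cohort <- manual_cohort(cancers$abbreviation, registry$symbol,
                            expr_tumor = mats, cnv = mats)
    hm <- gistic_heatmap(cohort, registry, cancers)
    expect_identical(names(hm)[-1],
                     sort_cancers_by_os(cancers)$abbreviation)
    for (cc in cancers$abbreviation) {
      for (g in registry$symbol) {
        expect_equal(hm[[cc]][hm$gene == g],
                     mean(as.numeric(mats[[cc]][mats[[cc]]$gene == g, -1])))
      }
    }
  }
})

test_that("heatmap columns follow the canonical OS order and report missing genes", {
  registry <- tibble::tibble(symbol = c("A", "B"), locality = "cytoplasmic",
                             family = "aaRS", msc_member = FALSE)
  cancers <- dplyr::filter(load_cancer_table(),
                           abbreviation %in% c("BRCA", "LAML"))
  zero <- gene_tbl(c("A", "B"), matrix(0L, 2, 3))
  cohort <- manual_cohort(c("BRCA", "LAML"), c("A", "B"),
                          expr_tumor = list(BRCA = zero, LAML = zero),
                          cnv = list(BRCA = zero, LAML = zero))
  hm <- gistic_heatmap(cohort, registry, cancers)
  expect_identical(names(hm), c("gene", "LAML", "BRCA"))
  expect_true(all(as.matrix(hm[, -1]) == 0))

  partial <- gene_tbl("A", matrix(0L, 1, 3))
  cohort2 <- manual_cohort(c("BRCA", "LAML"), c("A", "B"),
                           expr_tumor = list(BRCA = zero, LAML = partial),
                           cnv = list(BRCA = zero, LAML = partial))
  expect_error(gistic_heatmap(cohort2, registry, cancers), "LAML")
})

test_that("mutation tallies find clusters and treat spread-out hits as background", {
  muts <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         gene_symbol = "RARS2",
                         protein_position = c(6L, 6L, 6L),
                         consequence = "missense")
  tal <- mutation_position_tally(muts, "RARS2", protein_length = 578)
  expect_equal(tal$hotspots, tibble::tibble(residue = 6L, count = 3L))
  expect_equal(tal$counts$count[6], 3)
  expect_equal(sum(tal$counts$count), 3)

  spread <- tibble::tibble(sample_id = paste0("s", 1:10),
                           gene_symbol = "G",
                           protein_position = as.integer(1:10),
                           consequence = "missense")
  expect_equal(nrow(mutation_position_tally(spread, "G", 50)$hotspots), 0)

  empty <- spread[0, ]
  tal0 <- mutation_position_tally(empty, "G", 20)
  expect_equal(sum(tal0$counts$count), 0)
  expect_equal(nrow(tal0$hotspots), 0)

  expect_error(mutation_position_tally(spread, "G", 5), "exceeds")
})
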