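test_that("median split sends ties at the median to the low group", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 5)), c("low", "low", "low", "high"))
  expect_error(median_split(rep(7, 6)), "degenerate")
  expect_error(median_split(c(1, 2, 3)), "at least 4")
})

test_that("product-limit estimates match hand computation", {
  km <- km_estimate(surv_tbl(c(1, 2, 3), c(TRUE, TRUE, TRUE)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # censoring between events shrinks the risk set
  km2 <- km_estimate(surv_tbl(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 3], 0)  # 2/3 * (1 - 1/1)
  # censored-only data: survival stays at 1
  km3 <- km_estimate(surv_tbl(c(5, 8, 10), c(FALSE, FALSE, FALSE)))
  expect_true(all(km3$survival == 1))
  expect_error(km_estimate(surv_tbl(numeric(), logical())), "empty")
})

test_that("product-limit curve equals brute-force risk-set recomputation", {
  set.seed(14)
  for (i in 1:10) {
    tbl <- random_surv_tbl(sample(4:12, 1))
    km <- km_estimate(tbl)
    ref <- oracle_km(tbl$time_months, tbl$event)
    at_events <- km[km$n_event > 0, ]
    expect_equal(at_events$time, ref$time)
    expect_equal(at_events$survival, ref$survival, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
  }
})

test_that("log-rank agrees with the hypergeometric tabulation and its conventions", {
  hi <- surv_tbl(c(2, 4, 6, 8), c(1, 1, 0, 1), prefix = "h")
  lo <- surv_tbl(c(2, 4, 6, 8), c(1, 1, 0, 1), prefix = "l")
  lr <- logrank_test(hi, lo)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # small fixture vs independent hand tabulation
  hi2 <- surv_tbl(c(1, 3, 5, 7, 9, 11), c(1, 1, 0, 1, 1, 0), prefix = "h")
  lo2 <- surv_tbl(c(2, 4, 6, 8, 10, 12), c(1, 0, 1, 1, 0, 1), prefix = "l")
  lr2 <- logrank_test(hi2, lo2)
  ref <- oracle_logrank(hi2$time_months, hi2$event,
                        lo2$time_months, lo2$event)
  expect_equal(lr2$chi_square, ref$chi_square, tolerance = 1e-10)
  expect_equal(lr2$p_value, ref$p_value, tolerance = 1e-10)

  # rank invariance: scaling all times leaves the test unchanged
  scale3 <- function(tbl) dplyr::mutate(tbl, time_months = time_months * 3)
  lr3 <- logrank_test(scale3(hi2), scale3(lo2))
  expect_equal(lr3$chi_square, lr2$chi_square, tolerance = 1e-12)

  # zero events overall: vacuous test
  none <- surv_tbl(c(1, 2, 3, 4), rep(FALSE, 4))
  expect_equal(logrank_test(none, none), list(chi_square = 0, p_value = 1))
})

test_that("Mantel-Haenszel hazard ratio follows the O/E tabulation", {
  hi <- surv_tbl(c(2, 4, 6, 8), c(1, 1, 0, 1), prefix = "h")
  expect_equal(hazard_ratio(hi, dplyr::mutate(hi, sample_id = paste0(sample_id, "b"))), 1)

  set.seed(15)
  for (i in 1:10) {
    a <- random_surv_tbl(sample(5:12, 1), prefix = "a")
    b <- random_surv_tbl(sample(5:12, 1), prefix = "b")
    if (sum(a$event) == 0 || sum(b$event) == 0) next
    hr <- hazard_ratio(a, b)
    ref <- oracle_logrank(a$time_months, a$event, b$time_months, b$event)
    expect_equal(hr, ref$hr, tolerance = 1e-10)
    # swapping groups inverts the ratio and keeps the chi-square
    expect_equal(hazard_ratio(b, a), 1 / hr, tolerance = 1e-10)
    expect_equal(logrank_test(b, a)$chi_square,
                 logrank_test(a, b)$chi_square, tolerance = 1e-12)
  }

  # a group with zero observed deaths cannot support a ratio
  dead <- surv_tbl(c(1, 2, 3, 4), rep(TRUE, 4), prefix = "d")
  alive <- surv_tbl(c(5, 6, 7, 8), rep(FALSE, 4), prefix = "c")
  expect_true(is.na(hazard_ratio(dead, alive)))
})

test_that("survival map handles single cells, degenerate splits and missing tables", {
  set.seed(16)
  registry <- tibble::tibble(symbol = c("A", "B"), locality = "cytoplasmic",
                             family = "aaRS", msc_member = FALSE)
  cancers <- load_cancer_table()
  expr <- gene_tbl(c("A", "B"),
                   rbind(rlnorm(20, 3), rep(5, 20)))  # B is constant
  surv <- surv_tbl(round(rexp(20, 0.05) + 0.5, 1), runif(20) < 0.8)
  surv$sample_id <- colnames(expr)[-1]
  cohort <- manual_cohort("LAML", c("A", "B"), expr_tumor = list(LAML = expr),
                          survival = list(LAML = surv))
  sm <- survival_map(cohort, registry, cancers)
  resA <- sm$results[sm$results$gene == "A", ]
  resB <- sm$results[sm$results$gene == "B", ]
  expect_true(resA$evaluable)
  expect_equal(resA$q_value, resA$logrank_p)  # single evaluable cell: q = p
  expect_false(resB$evaluable)
  expect_equal(resB$direction, "ns")

  cohort2 <- manual_cohort(c("LAML", "BRCA"), c("A", "B"),
                           expr_tumor = list(LAML = expr, BRCA = expr),
                           survival = list(LAML = surv, BRCA = NULL))
  expect_warning(sm2 <- survival_map(cohort2, registry, cancers), "BRCA")
  expect_identical(sm2$not_evaluable, "BRCA")
})

test_that("the planted driver's hazard ratio is recovered from a full cohort", {
  cohort <- generate_cohort(default_config("paper_like"))
  cfg <- cohort$config
  cancer <- cfg$cancers[1]
  driver <- cfg$driver_map[[cancer]]
  expect_equal(cfg$archetype[[driver]], "oncogene_like")
  d <- cohort$data[[cancer]]
  expr <- as.numeric(d$expr_tumor[d$expr_tumor$gene == driver, -1])
  grp <- median_split(expr)
  hr <- hazard_ratio(d$survival[grp == "high", ], d$survival[grp == "low", ])
  expect_lt(abs(log(hr) - cfg$log_hr_per_group[["oncogene_like"]]), 0.3)
})

test_that("aggressiveness correlation reproduces exact linear fixtures", {
  cancers <- tibble::tibble(abbreviation = paste0("C", 1:5),
                            full_name = paste0("C", 1:5),
                            median_os_months = c(10, 20, 30, 40, 50))
  up <- tibble::tibble(cancer = cancers$abbreviation,
                       n_up = cancers$median_os_months * 2)
  res <- aggressiveness_correlation(cancers, up)
  expect_equal(res$pearson_r, 1)

  up_neg <- tibble::tibble(cancer = paste0("C", 1:3), n_up = c(3, 2, 1))
  res2 <- aggressiveness_correlation(cancers[1:3, ], up_neg)
  expect_equal(res2$pearson_r, -1)

  # exclusion drops the named cancers before correlating
  res3 <- aggressiveness_correlation(cancers, up, exclude = "C1")
  expect_equal(res3$n, 4)
  expect_error(aggressiveness_correlation(cancers[1:2, ], up[1:2, ]),
               "at least 3")
})
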