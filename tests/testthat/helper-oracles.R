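# Independent brute-force oracles used to validate the statistical cores.
# These deliberately avoid the code paths (and packages) they check.

# Benjamini-Hochberg by the literal min-over-tail definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / seq(i, m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Product-limit estimator by explicit risk-set recomputation.
# Returns survival at each distinct event time.
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ev_times, survival = surv)
}

# Two-group log-rank by per-event-time 2x2 tabulation under the
# hypergeometric null; also returns the O/E accumulations for the
# Mantel-Haenszel hazard ratio.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1], t2[e2])))
  O1 <- E1 <- O2 <- E2 <- V <- 0
  for (t in times) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & e1); d2 <- sum(t2 == t & e2); d <- d1 + d2
    O1 <- O1 + d1; O2 <- O2 + d2
    E1 <- E1 + d * n1 / n; E2 <- E2 + d * n2 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi_square = chisq,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
       hr = (O1 / E1) / (O2 / E2))
}

# Pooled-variance one-way ANOVA F-test for two groups, computed from the
# mean-square definitions.
oracle_anova_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  gm <- mean(c(x, y))
  msb <- (n1 * (mean(x) - gm)^2 + n2 * (mean(y) - gm)^2) / 1
  msw <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n - 2)
  f <- msb / msw
  pf(f, 1, n - 2, lower.tail = FALSE)
}

surv_tbl <- function(time, event, prefix = "s") {
  tibble::tibble(sample_id = paste0(prefix, seq_along(time)),
                 time_months = time, event = as.logical(event))
}

random_surv_tbl <- function(n, prefix = "s") {
  surv_tbl(round(rexp(n, 0.1) + 0.5, 1), runif(n) < 0.7, prefix = prefix)
}

# Minimal hand-built cohort for map-level tests.
manual_cohort <- function(cancers, genes, expr_tumor, expr_normal = NULL,
                          cnv = NULL, survival = NULL, mutations = NULL) {
  data <- lapply(cancers, function(cancer) {
    et <- expr_tumor[[cancer]]
    cnv_c <- cnv[[cancer]]
    if (is.null(cnv_c)) {
      cnv_c <- dplyr::mutate(et, dplyr::across(-gene, ~ 0L))
    }
    list(
      cnv = cnv_c,
      mutations = mutations[[cancer]] %||%
        tibble::tibble(sample_id = character(), gene_symbol = character(),
                       protein_position = integer(),
                       consequence = character()),
      expr_tumor = et,
      expr_normal = expr_normal[[cancer]],
      survival = survival[[cancer]],
      driver = NA_character_
    )
  })
  names(data) <- cancers
  structure(list(config = NULL, cancers = cancers, data = data),
            class = "aars_cohort")
}

gene_tbl <- function(genes, mat, prefix = "s") {
  colnames(mat) <- paste0(prefix, seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(mat))
}

`%||%` <- rlang::`%||%`
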