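slope_fixture <- function(beta_rows, passages, genes = NULL,
                          island = TRUE) {
  n <- nrow(beta_rows)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(n))
  samples <- data.frame(
    sample_id = colnames(beta_rows), cell_line = "x", passage = passages,
    sex = "female", cell_type = "hESC", qc_pass = TRUE,
    stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = rownames(beta_rows), gene = genes,
                    chromosome = "1", position = seq_len(n) * 1000,
                    in_cpg_island = island, platform = "meth450k",
                    stringsAsFactors = FALSE)
  list(beta = beta_rows, samples = samples, ann = ann)
}

test_that("ols recovers an exact linear methylation-passage relationship", {
  p <- c(10, 20, 30, 40)
  b <- rbind(line = 0.1 + 0.004 * p, flat = rep(0.3, 4))
  colnames(b) <- sprintf("s%d", 1:4)
  fx <- slope_fixture(b, p)
  fit <- fit_methylation_slopes(fx$beta, fx$samples, fx$ann)
  r <- fit$records
  expect_equal(r$slope[r$probe_id == "line"], 0.004, tolerance = 1e-12)
  expect_equal(r$intercept[r$probe_id == "line"], 0.1, tolerance = 1e-12)
  expect_equal(r$slope[r$probe_id == "flat"], 0, tolerance = 1e-12)

  # missing values are excluded pairwise, not imputed
  b2 <- b; b2["line", 2] <- NA
  fit2 <- fit_methylation_slopes(b2, fx$samples, fx$ann)
  expect_equal(fit2$records$slope[1], 0.004, tolerance = 1e-12)
  expect_identical(fit2$records$n_samples[1], 3L)

  expect_error(
    fit_methylation_slopes(b, within(fx$samples, passage <- 10), fx$ann),
    "distinct passage")
})

test_that("slopes negate exactly under beta -> 1 - beta", {
  set.seed(31)
  p <- rep(c(5, 20, 50, 80), 3)
  b <- matrix(runif(10 * 12, 0.2, 0.8), 10, 12,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%d", 1:12)))
  fx <- slope_fixture(b, p)
  s1 <- fit_methylation_slopes(fx$beta, fx$samples, fx$ann)$records$slope
  s2 <- fit_methylation_slopes(1 - fx$beta, fx$samples, fx$ann)$records$slope
  expect_equal(s2, -s1, tolerance = 1e-12)
})

test_that("ranking orders slopes, shares ties, and ignores gene-less probes", {
  p <- c(10, 20, 30, 40)
  slopes <- c(a = 0.01, b = 0.002, c = 0, d = -0.003)
  b <- t(vapply(slopes, function(s) 0.3 + s * p, numeric(4)))
  colnames(b) <- sprintf("s%d", 1:4)
  fx <- slope_fixture(b, p, genes = c("g1", "g2", "g3", "g4"))
  fit <- fit_methylation_slopes(fx$beta, fx$samples, fx$ann)
  rk <- rank_slopes(fit)
  expect_identical(rk$records$probe_id, c("a", "b", "c", "d"))
  expect_identical(rk$records$rank, 1:4)

  # gene-less probes are excluded from the ranking universe
  fx2 <- slope_fixture(b, p, genes = c("g1", "", "g3", "g4"))
  rk2 <- rank_slopes(fit_methylation_slopes(fx2$beta, fx2$samples, fx2$ann))
  expect_identical(rk2$universe_size, 3L)

  # equal slopes share the percentile; deterministic order is by probe id
  b3 <- matrix(0.3, 4, 4, dimnames = dimnames(b))
  rk3 <- rank_slopes(fit_methylation_slopes(b3, fx$samples, fx$ann))
  expect_identical(unique(rk3$records$percentile), 100)
  expect_identical(rk3$records$probe_id, sort(rownames(b3)))

  # percentile is invariant under adding a constant to all slopes
  b4 <- b + outer(rep(0.002, 4), p)   # adds 0.002 to every slope
  rk4 <- rank_slopes(fit_methylation_slopes(b4, fx$samples, fx$ann))
  expect_identical(rk4$records$percentile, rk$records$percentile)
})

test_that("drift island probes rank at the very top of the slope universe", {
  d <- simulate_dataset(tiny_config(seed = 32, n_genes = 1000,
                                    n_drift_genes = 10))
  fit <- fit_methylation_slopes(d$beta, d$samples, d$annotation)
  rk <- rank_slopes(fit, candidate_genes = d$truth$drift_genes)
  cs <- rk$candidate_summary
  island <- cs[cs$in_cpg_island == TRUE, ]
  sea <- cs[cs$in_cpg_island == FALSE, ]
  expect_gte(island$frac_top, 0.9)       # top 1% of ~2000 probes
  expect_lt(abs(sea$mean_slope), 5e-4)   # open-sea probes stay stable
})

test_that("variance ranking is permutation-invariant and flags constants", {
  set.seed(33)
  m <- matrix(rnorm(50, 8), 5, 10,
              dimnames = list(sprintf("e%d", 1:5), sprintf("s%d", 1:10)))
  m["e3", ] <- 7.5  # constant row
  b <- matrix(runif(50), 5, 10,
              dimnames = list(sprintf("m%d", 1:5), sprintf("s%d", 1:10)))
  ann <- data.frame(probe_id = c(rownames(m), rownames(b)),
                    gene = rep(sprintf("g%d", 1:5), 2),
                    chromosome = "1", position = 1:10 * 100,
                    in_cpg_island = TRUE,
                    platform = rep(c("expr_array", "meth27k"), each = 5),
                    stringsAsFactors = FALSE)
  vr <- variability_ranking(m, b, ann)
  e <- vr$expression
  expect_identical(e$probe_id[e$rank == 5L], "e3")
  expect_equal(e$variance[e$rank == 5L], 0)

  perm <- sample(10)
  vr2 <- variability_ranking(m[, perm], b[, perm], ann)
  expect_equal(vr2$expression$variance, vr$expression$variance)
  expect_equal(vr2$methylation$variance, vr$methylation$variance)
})

test_that("drift genes land in the top variance decile of both data kinds", {
  d <- simulate_dataset(tiny_config(seed = 34, n_genes = 1000,
                                    n_drift_genes = 10))
  vr <- variability_ranking(d$expr, d$beta, d$annotation,
                            candidate_genes = d$truth$drift_genes)
  top_e <- vr$expression$gene[vr$expression$percentile <= 10]
  top_m <- vr$methylation$gene[vr$methylation$percentile <= 10]
  expect_true(all(d$truth$drift_genes %in% top_e))
  expect_true(all(d$truth$drift_genes %in% top_m))
  expect_lt(vr$enrichment$expression$p_value, 1e-6)
  expect_lt(vr$enrichment$methylation$p_value, 1e-6)
})
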