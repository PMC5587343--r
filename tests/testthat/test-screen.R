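test_that("group assignment honors the passage cutoffs of both designs", {
  st <- data.frame(sample_id = c("a", "b", "c", "d"), cell_line = "x",
                   passage = c(25, 30, 50, 10), sex = "female",
                   cell_type = "hESC", qc_pass = TRUE,
                   stringsAsFactors = FALSE)
  gs <- assign_groups(st, "strict")
  expect_identical(gs$label, c("low", "excluded", "high", "low"))
  gp <- assign_groups(st, "permissive")
  expect_identical(gp$label, c("low", "high", "high", "low"))

  st$qc_pass <- c(TRUE, TRUE, FALSE, TRUE)
  expect_error(assign_groups(st, "strict"), "empty passage group")
  st2 <- st; st2$passage <- c(10, 15, 20, 22)
  expect_error(assign_groups(st2, "strict"), "empty passage group")
})

test_that("candidate calling uses strict cutoff inequalities", {
  fx <- manual_screen_fixture()
  groups <- assign_groups(fx$samples)
  sc <- drift_screen(fx$beta, fx$expr, fx$annotation, groups)
  r <- sc$records[match(c("m1", "m2", "m3"), sc$records$probe_id), ]
  expect_equal(r$delta_beta, c(0.25, 0.20, 0.25), tolerance = 1e-12)
  expect_equal(r$expr_fold, c(2, 2, 1.5), tolerance = 1e-12)
  expect_identical(r$candidate, c(TRUE, FALSE, FALSE))
  expect_identical(candidate_gene_set(sc), "g1")
})

test_that("screen recovers planted drift genes exactly on noise-free data", {
  # high expression baseline keeps silenced values off the floor, so the
  # planted coupling is exactly linear
  cfg <- noise_free_config(seed = 21, expr_baseline_mean = 12)
  d <- simulate_dataset(cfg)
  g <- assign_groups(d$samples, require_qc = FALSE)
  f <- filter_probes(d$beta, d$expr, d$annotation, g)
  sc <- drift_screen(f$beta, f$expr, d$annotation, g)
  expect_setequal(candidate_gene_set(sc), d$truth$drift_genes)
  # negative methylation-expression coupling: correlation at -1 up to clipping
  drift_rec <- sc$records[sc$records$candidate, ]
  expect_true(all(drift_rec$meth_expr_corr <= -0.99))
  # non-drift records show no spurious candidates
  expect_identical(sum(sc$records$candidate),
                   nrow(drift_rec))
})

test_that("screen is invariant to sample order and aggregate choice on symmetric data", {
  fx <- manual_screen_fixture()
  groups <- assign_groups(fx$samples)
  sc1 <- drift_screen(fx$beta, fx$expr, fx$annotation, groups)
  perm <- c(4, 2, 6, 1, 3, 5)
  sc2 <- drift_screen(fx$beta[, perm], fx$expr[, perm], fx$annotation,
                      groups)
  expect_equal(sc1$records, sc2$records)
  # within-group-constant data: mean and median aggregates coincide
  sc_med <- drift_screen(fx$beta, fx$expr, fx$annotation, groups,
                         beta_aggregate = "median",
                         expr_aggregate = "mean")
  expect_equal(sc_med$records$delta_beta, sc1$records$delta_beta)
  expect_equal(sc_med$records$expr_fold, sc1$records$expr_fold)
})

test_that("probes with too few samples per group are unevaluable", {
  fx <- manual_screen_fixture()
  groups <- assign_groups(fx$samples)
  beta <- fx$beta
  beta["m1", c("s1", "s2")] <- NA  # one low-group sample left
  sc <- drift_screen(beta, fx$expr, fx$annotation, groups)
  r <- sc$records[sc$records$probe_id == "m1", ]
  expect_false(r$evaluable)
  expect_false(r$candidate)
})

test_that("gene collapse maps candidate probes many-to-one", {
  records <- data.frame(
    probe_id = c("p1", "p2", "p3"), gene = c("g1", "g1", "g2"),
    candidate = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  expect_identical(candidate_gene_set(records), "g1")
  records$candidate <- FALSE
  expect_identical(candidate_gene_set(records), character(0))
})

test_that("compendium validation flags silenced genes and honors FDR", {
  # identical group distributions: maximal p
  st <- data.frame(sample_id = sprintf("s%d", 1:12), cell_line = "x",
                   passage = rep(c(10, 60), 6), sex = "female",
                   cell_type = "hESC", qc_pass = TRUE,
                   stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = "e1", gene = "g1", chromosome = "1",
                    position = 1, in_cpg_island = FALSE,
                    platform = "expr_array", stringsAsFactors = FALSE)
  m <- matrix(rep(c(5, 7, 9, 5, 7, 9, 5, 7, 9, 5, 7, 9), 1), 1,
              dimnames = list("e1", st$sample_id))
  v0 <- validate_expression_compendium(m, st, "g1", ann)
  expect_gt(v0$probes$p, 0.99)
  expect_false(v0$genes$validated)

  # planted drift genes are recovered at q < 0.05
  d <- simulate_dataset(tiny_config(seed = 22))
  f <- filter_probes(d$beta, d$expr, d$annotation,
                     assign_groups(d$samples, require_qc = FALSE))
  v <- validate_expression_compendium(f$expr, d$samples,
                                      d$truth$drift_genes, d$annotation)
  expect_true(all(v$genes$validated))
  expect_true(all(v$probes$q < 0.05))
})
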