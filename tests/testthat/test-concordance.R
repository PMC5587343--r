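# Independent log-gamma implementation of the upper hypergeometric tail,
# used as a cross-check oracle for intersect_candidates().
hyper_tail_lgamma <- function(k, size_a, size_b, universe) {
  lchoose_ <- function(n, r) lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
  kk <- k:min(size_a, size_b)
  terms <- lchoose_(size_a, kk) + lchoose_(universe - size_a, size_b - kk) -
    lchoose_(universe, size_b)
  mx <- max(terms)
  exp(mx) * sum(exp(terms - mx))
}

test_that("overlap probability matches exact enumeration on small universes", {
  res <- intersect_candidates(letters[1:5], letters[1:5], universe = 20)
  expect_identical(res$overlap_size, 5L)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # disjoint sets: P(X >= 0) = 1
  res0 <- intersect_candidates(c("a", "b"), c("c", "d"), universe = 20)
  expect_identical(res0$overlap_size, 0L)
  expect_equal(res0$p_value, 1)

  expect_error(intersect_candidates(letters[1:10], letters[11:20],
                                    universe = 15), "universe")
})

test_that("overlap probability matches a log-gamma oracle to 6 significant digits", {
  a <- sprintf("a%02d", 1:19)
  b <- c(a[1:10], sprintf("b%02d", 1:30))   # |a|=19, |b|=40, overlap 10
  for (universe in c(2000, 5000, 10000, 20000)) {
    got <- intersect_candidates(a, b, universe = universe)$p_value
    want <- hyper_tail_lgamma(10, 19, 40, universe)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("overlap probability is monotone in overlap size and matches Monte Carlo", {
  universe_genes <- sprintf("u%03d", 1:50)
  ps <- vapply(0:5, function(k) {
    a <- universe_genes[1:5]
    b <- c(a[seq_len(k)], universe_genes[40:(44 - k + 1)])[1:5]
    intersect_candidates(a, b, universe = 50)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))

  # permutation oracle for a moderate-p instance
  set.seed(41)
  a <- universe_genes[1:5]
  b <- universe_genes[c(1, 10:13)]          # overlap 1
  p_exact <- intersect_candidates(a, b, universe = 50)$p_value
  draws <- replicate(20000,
                     length(intersect(sample(universe_genes, 5), a)) >= 1)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(mean(draws) - p_exact), 3 * se)
})

# Enumeration oracle for the two-tailed Fisher exact test: sum of the
# probabilities of all tables with the observed margins whose probability
# does not exceed the observed table's.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

branch_test_from_table <- function(a, b, c, d) {
  ids <- sprintf("s%02d", seq_len(a + b + c + d))
  branches <- stats::setNames(rep(c(1, 2), c(a + b, c + d)), ids)
  groups <- stats::setNames(rep(c("low", "high", "low", "high"),
                                c(a, b, c, d)), ids)
  branch_composition_test(branches, groups)
}

test_that("branch composition test reproduces exact enumeration values", {
  t1 <- branch_test_from_table(5, 0, 0, 5)
  expect_equal(t1$fisher_p, 2 / choose(10, 5), tolerance = 1e-12)
  t2 <- branch_test_from_table(3, 3, 3, 3)
  expect_equal(t2$fisher_p, 1)
  # swapping branch labels leaves p unchanged
  t3 <- branch_test_from_table(0, 5, 5, 0)
  expect_equal(t3$fisher_p, t1$fisher_p, tolerance = 1e-12)
  # degenerate margin: all samples in one passage group
  expect_warning(
    t4 <- branch_composition_test(
      stats::setNames(c(1, 1, 2, 2), sprintf("s%d", 1:4)),
      stats::setNames(rep("low", 4), sprintf("s%d", 1:4))),
    "degenerate")
  expect_equal(t4$fisher_p, 1)
})

test_that("fisher p matches full enumeration for all tables up to n = 20", {
  for (n in c(7, 12, 20)) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        for (a in max(0, r1 + c1 - n):min(r1, c1)) {
          b <- r1 - a; c <- c1 - a; d <- n - r1 - c1 + a
          got <- branch_test_from_table(a, b, c, d)$fisher_p
          expect_equal(got, fisher_enum(a, b, c, d), tolerance = 1e-9,
                       label = sprintf("table [%d,%d;%d,%d]", a, b, c, d))
        }
      }
    }
  }
})

test_that("clustering separates planted groups and behaves as a metric", {
  cfg <- noise_free_config(seed = 42, n_genes = 200, n_drift_genes = 40,
                           expr_baseline_mean = 12)
  d <- simulate_dataset(cfg)
  g <- assign_groups(d$samples, require_qc = FALSE)
  cl <- hierarchical_cluster(d$beta, "pearson")
  lab <- stats::setNames(g$label, g$sample_id)[names(cl$branches)]
  # branches must coincide with the true passage groups (either labeling)
  agreement <- mean((cl$branches == 1) == (lab == "low"))
  expect_true(agreement %in% c(0, 1))
  tt <- branch_composition_test(cl, g, "methylation")
  expect_lt(tt$fisher_p, 1e-10)

  # duplicate samples sit at zero distance in the same leaf cluster
  m <- d$expr[, 1:6]
  m[, 6] <- m[, 5]
  colnames(m)[6] <- "dup"
  dmat <- as.matrix(stats::dist(t(unclass(m))))
  expect_equal(unname(dmat[5, 6]), 0)
  expect_true(all(abs(dmat - t(dmat)) < 1e-12) && all(diag(dmat) == 0))
  cl2 <- hierarchical_cluster(m, "euclidean")
  merge_height <- cl2$hclust$height[1]
  expect_equal(merge_height, 0)

  # constant profile is rejected under pearson distance
  bad <- d$expr[, 1:5]; bad[, 3] <- 7
  colnames(bad)[3] <- "flat"
  expect_error(hierarchical_cluster(bad, "pearson"), "flat")
})

test_that("stratified clustering respects strata and reduces to plain clustering", {
  d <- simulate_dataset(tiny_config(seed = 43, n_genes = 300,
                                    n_drift_genes = 30))
  g <- assign_groups(d$samples, require_qc = FALSE)
  res <- stratified_clustering(d$beta, d$samples, g, stratify_by = "sex",
                               data_kind = "methylation")
  expect_setequal(names(res), c("female", "male"))
  for (s in names(res)) {
    ids <- names(res[[s]]$clustering$branches)
    expect_true(all(d$samples$sex[match(ids, d$samples$sample_id)] == s))
    expect_lt(res[[s]]$test$fisher_p, 0.05)
  }

  plain <- stratified_clustering(d$beta, d$samples, g, stratify_by = "none",
                                 data_kind = "methylation")
  direct <- hierarchical_cluster(d$beta, "pearson")
  expect_identical(plain$all$clustering$branches, direct$branches)

  one_sex <- d$samples; one_sex$sex <- "female"
  res1 <- stratified_clustering(d$beta, one_sex, g, stratify_by = "sex",
                                data_kind = "methylation")
  expect_identical(names(res1), "female")
})

test_that("dendrograms export as newick", {
  d <- simulate_dataset(tiny_config(seed = 44, n_genes = 100))
  cl <- hierarchical_cluster(d$expr[, 1:10], "euclidean")
  path <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(d$expr)[1:10])
})
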