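# Small simulation configs used across test files.

tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_lines = 4, n_genes = 300, n_drift_genes = 5, seed = seed), list(...))
  do.call(sim_config, args)
}

noise_free_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, beta_noise_sd = 0, expr_noise_sd = 0,
              frac_unexpressed = 0, ...)
}

# hand-built 3-probe x 4-sample dataset with known group statistics
manual_screen_fixture <- function() {
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    cell_line = rep(c("A", "B"), each = 3),
    passage = c(10, 15, 20, 60, 70, 80),
    sex = "female", cell_type = "hESC", qc_pass = TRUE,
    stringsAsFactors = FALSE)
  annotation <- data.frame(
    probe_id = c("m1", "m2", "m3", "e1", "e2", "e3"),
    gene = c("g1", "g2", "g3", "g1", "g2", "g3"),
    chromosome = "1", position = c(1, 101, 201, 1, 101, 201) * 1000,
    in_cpg_island = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    platform = c(rep("meth27k", 3), rep("expr_array", 3)),
    stringsAsFactors = FALSE)
  # g1: delta-beta 0.25, fold 2     -> candidate
  # g2: delta-beta 0.20, fold 2     -> not (strict boundary)
  # g3: delta-beta 0.25, fold 1.5   -> not (strict boundary)
  beta <- rbind(
    m1 = c(0.10, 0.10, 0.10, 0.35, 0.35, 0.35),
    m2 = c(0.10, 0.10, 0.10, 0.30, 0.30, 0.30),
    m3 = c(0.10, 0.10, 0.10, 0.35, 0.35, 0.35))
  expr <- rbind(
    e1 = c(8, 8, 8, 7, 7, 7),
    e2 = c(8, 8, 8, 7, 7, 7),
    e3 = c(8, 8, 8, 8 - log2(1.5), 8 - log2(1.5), 8 - log2(1.5)))
  colnames(beta) <- colnames(expr) <- samples$sample_id
  list(beta = beta,
       expr = apply_expression_floor(expr, 4),
       samples = samples, annotation = annotation)
}
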