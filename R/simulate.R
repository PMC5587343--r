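#' Configuration for the synthetic methylation/expression generator
#'
#' Builds the parameter list consumed by \code{\link{simulate_dataset}}. The
#' defaults emulate a matched methylation + expression compendium of cultured
#' pluripotent stem-cell lines sampled across a wide passage range: 6 lines
#' profiled at 10 passages each (30 samples at passage 25 or below, 30 at
#' passage 50 or above), 10,000 genes with one CpG-island and one open-sea
#' methylation probe each, and 20 planted "drift" genes whose island
#' methylation rises linearly with passage while their expression is silenced
#' in proportion to the realized methylation gain.
#'
#' @param n_lines Number of cell lines.
#' @param passages_per_line Integer vector of passages at which every line is
#'   profiled.
#' @param n_genes Number of genes.
#' @param probes_per_gene Methylation probes per gene; the first
#'   \code{ceiling(probes_per_gene / 2)} are CpG-island probes, the rest
#'   open sea.
#' @param n_drift_genes Number of planted passage-drift genes.
#' @param drift_slope True methylation slope of drift-gene island probes, in
#'   beta units per passage.
#' @param drift_expr_log2fc Expected log2 expression loss of a drift gene
#'   between the low-passage (<= 25) and high-passage (>= 50) groups; each
#'   sample's silencing is scaled by its own realized methylation gain, so
#'   methylation and expression are negatively correlated by construction.
#' @param beta_noise_sd Beta measurement noise (added to the clipped linear
#'   predictor, then re-clipped to \eqn{[0,1]}).
#' @param expr_noise_sd Expression noise, log2 units.
#' @param expr_floor Log2 expression floor applied to the generated matrix.
#' @param expr_baseline_mean,expr_baseline_sd Log2 baseline expression
#'   distribution across genes.
#' @param frac_unexpressed Fraction of genes planted below the floor in all
#'   samples (exercises the unexpressed-gene filter).
#' @param n_aneuploid_samples Number of samples given a chromosome-scale
#'   expression shift (trisomy-like).
#' @param aneuploid_log2fc Log2 shift applied to every gene on the chosen
#'   chromosome of an aneuploid sample; default \code{log2(1.5)}, the
#'   expected dosage effect of a trisomy.
#' @param aneuploid_chromosome Chromosome receiving the shift (default
#'   \code{"12"}, a recurrent trisomy in cultured pluripotent cells).
#' @param platform_overlap_fraction Fraction of genes shared with a second
#'   platform (see \code{\link{simulate_second_platform}}).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_lines = 6,
                       passages_per_line = c(5, 10, 15, 20, 25,
                                             70, 80, 90, 100, 110),
                       n_genes = 10000,
                       probes_per_gene = 2,
                       n_drift_genes = 20,
                       drift_slope = 0.004,
                       drift_expr_log2fc = 3,
                       beta_noise_sd = 0.05,
                       expr_noise_sd = 0.5,
                       expr_floor = 4,
                       expr_baseline_mean = 8,
                       expr_baseline_sd = 1.5,
                       frac_unexpressed = 0.02,
                       n_aneuploid_samples = 0,
                       aneuploid_log2fc = log2(1.5),
                       aneuploid_chromosome = "12",
                       platform_overlap_fraction = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$passages_per_line) == 0)
    stop("passages_per_line must be non-empty")
  stopifnot(cfg$n_drift_genes <= cfg$n_genes,
            cfg$probes_per_gene >= 1,
            cfg$beta_noise_sd >= 0, cfg$expr_noise_sd >= 0,
            cfg$drift_slope >= 0,
            cfg$platform_overlap_fraction >= 0,
            cfg$platform_overlap_fraction <= 1,
            cfg$n_aneuploid_samples <= cfg$n_lines *
              length(cfg$passages_per_line))
  class(cfg) <- "sim_config"
  cfg
}

# Run expr with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Gene -> chromosome weights roughly proportional to real gene density.
chrom_weights <- function() {
  w <- c(10, 7, 6, 5, 5, 5, 5, 4, 4, 4, 6, 5, 2, 3, 3, 4, 6, 2, 7, 3, 2, 3,
         4, 0.5)
  names(w) <- CHROMOSOMES
  w
}

# Expected group-mean beta gain of a drift probe under the strict passage
# grouping; used to scale expression silencing per realized beta unit.
drift_beta_span <- function(cfg) {
  p <- cfg$passages_per_line
  low <- p[p <= 25]; high <- p[p >= 50]
  if (length(low) == 0 || length(high) == 0) {
    span <- cfg$drift_slope * diff(range(p))
  } else {
    span <- cfg$drift_slope * (mean(high) - mean(low))
  }
  if (span <= 0) 1 else span
}

sim_gene_table <- function(cfg) {
  gene <- sprintf("G%05d", seq_len(cfg$n_genes))
  chromosome <- sample(CHROMOSOMES, cfg$n_genes, replace = TRUE,
                       prob = chrom_weights())
  drift <- rep(FALSE, cfg$n_genes)
  autosomal <- which(!(chromosome %in% c("X", "Y")))
  drift[sample(autosomal, cfg$n_drift_genes)] <- TRUE
  # drift genes never on the chromosome used for aneuploidy injection, so a
  # trisomy-like shift touches only its own chromosome's baseline genes
  clash <- which(drift & chromosome == cfg$aneuploid_chromosome)
  if (length(clash) > 0)
    chromosome[clash] <- sample(setdiff(CHROMOSOMES[1:22],
                                        cfg$aneuploid_chromosome),
                                length(clash), replace = TRUE)
  position <- integer(cfg$n_genes)
  for (ch in unique(chromosome)) {
    i <- which(chromosome == ch)
    position[i] <- seq_along(i) * 100000L
  }
  unexpr <- rep(FALSE, cfg$n_genes)
  n_un <- round(cfg$frac_unexpressed * cfg$n_genes)
  if (n_un > 0)
    unexpr[sample(which(!drift), n_un)] <- TRUE
  data.frame(gene = gene, chromosome = chromosome, position = position,
             drift = drift, unexpressed = unexpr,
             stringsAsFactors = FALSE)
}

sim_samples <- function(cfg, line_prefix = "L") {
  lines <- sprintf("%s%02d", line_prefix, seq_len(cfg$n_lines))
  df <- expand.grid(passage = cfg$passages_per_line, cell_line = lines,
                    stringsAsFactors = FALSE)[, c("cell_line", "passage")]
  df$sample_id <- sprintf("%s_p%03d", df$cell_line, df$passage)
  df$sex <- ifelse(match(df$cell_line, lines) %% 2 == 0, "male", "female")
  df$cell_type <- ifelse(match(df$cell_line, lines) <= ceiling(cfg$n_lines * 2 / 3),
                         "hESC", "hiPSC")
  df$qc_pass <- NA
  df[, c("sample_id", "cell_line", "passage", "sex", "cell_type", "qc_pass")]
}

# Core generator shared by both platforms: one gene table in, one matched
# beta/expression dataset out.
sim_generate <- function(cfg, genes, samples, meth_prefix, expr_prefix,
                         meth_platform) {
  ng <- nrow(genes); ns <- nrow(samples); ppg <- cfg$probes_per_gene
  n_island <- ceiling(ppg / 2)
  island_flag <- rep(c(rep(TRUE, n_island), rep(FALSE, ppg - n_island)), ng)
  gene_idx <- rep(seq_len(ng), each = ppg)
  probe_id <- sprintf("%s%07d", meth_prefix, seq_len(ng * ppg))

  beta0 <- ifelse(island_flag,
                  stats::rbeta(ng * ppg, 2, 18),
                  stats::rbeta(ng * ppg, 17, 3))
  slope <- ifelse(island_flag & genes$drift[gene_idx], cfg$drift_slope, 0)
  p <- samples$passage
  mu <- outer(beta0, rep(1, ns)) + outer(slope, p)
  mu[mu < 0] <- 0; mu[mu > 1] <- 1
  beta <- mu
  if (cfg$beta_noise_sd > 0)
    beta <- beta + stats::rnorm(length(beta), sd = cfg$beta_noise_sd)
  beta[beta < 0] <- 0; beta[beta > 1] <- 1
  dimnames(beta) <- list(probe_id, samples$sample_id)

  e0 <- stats::rnorm(ng, cfg$expr_baseline_mean, cfg$expr_baseline_sd)
  e0[genes$unexpressed] <- cfg$expr_floor - 2
  # silencing is driven by each sample's realized island beta gain, so the
  # methylation-expression correlation of drift genes is negative by design
  coupling <- cfg$drift_expr_log2fc / drift_beta_span(cfg)
  first_island <- match(seq_len(ng), gene_idx[island_flag])
  island_beta <- beta[which(island_flag)[first_island], , drop = FALSE]
  gain <- island_beta - beta0[which(island_flag)[first_island]]
  gain[gain < 0] <- 0
  gain[!genes$drift, ] <- 0
  expr <- outer(e0, rep(1, ns)) - coupling * gain
  if (cfg$expr_noise_sd > 0)
    expr <- expr + stats::rnorm(length(expr), sd = cfg$expr_noise_sd)
  expr_probe <- sprintf("%s%07d", expr_prefix, seq_len(ng))
  dimnames(expr) <- list(expr_probe, samples$sample_id)

  aneuploid <- data.frame(sample_id = character(0), chromosome = character(0),
                          log2fc = numeric(0), stringsAsFactors = FALSE)
  if (cfg$n_aneuploid_samples > 0) {
    tgt <- sample(samples$sample_id, cfg$n_aneuploid_samples)
    on_chr <- genes$chromosome == cfg$aneuploid_chromosome
    expr[on_chr, tgt] <- expr[on_chr, tgt] + cfg$aneuploid_log2fc
    aneuploid <- data.frame(sample_id = tgt,
                            chromosome = cfg$aneuploid_chromosome,
                            log2fc = cfg$aneuploid_log2fc,
                            stringsAsFactors = FALSE)
  }
  expr <- apply_expression_floor(as_expr_matrix(expr), cfg$expr_floor)

  annotation <- rbind(
    data.frame(probe_id = probe_id, gene = genes$gene[gene_idx],
               chromosome = genes$chromosome[gene_idx],
               position = genes$position[gene_idx] +
                 500L * ((seq_len(ng * ppg) - 1L) %% ppg),
               in_cpg_island = island_flag, platform = meth_platform,
               stringsAsFactors = FALSE),
    data.frame(probe_id = expr_probe, gene = genes$gene,
               chromosome = genes$chromosome, position = genes$position,
               in_cpg_island = FALSE, platform = "expr_array",
               stringsAsFactors = FALSE)
  )

  truth <- list(
    drift_genes = genes$gene[genes$drift],
    aneuploid_samples = aneuploid,
    true_slopes = stats::setNames(slope, probe_id)
  )
  list(beta = as_beta_matrix(beta), expr = expr, samples = samples,
       annotation = annotation, truth = truth)
}

#' Simulate a matched methylation/expression dataset with planted drift genes
#'
#' Generates a probe-by-sample beta matrix, a matched log2 expression matrix,
#' sample metadata, probe annotation and the ground truth of what was
#' planted. CpG-island probes of non-drift genes draw their baselines from a
#' low-beta mode (Beta(2,18), mean 0.1) and open-sea probes from a high-beta
#' mode (Beta(17,3), mean 0.85). Drift-gene island probes follow
#' \eqn{\beta(p) = \mathrm{clip}(\beta_0 + s\,p) + \epsilon} with measurement
#' noise re-clipped to \eqn{[0,1]}, and the gene's expression drops in
#' proportion to the sample's realized methylation gain. Optionally, a subset
#' of samples receives a uniform log2 expression shift on one autosome,
#' emulating a trisomy.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A list with elements \code{beta}, \code{expr}, \code{samples},
#'   \code{annotation} and \code{truth} (drift genes, aneuploid samples,
#'   per-probe true slopes).
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 200, n_drift_genes = 3,
#'                                  seed = 7))
#' d$truth$drift_genes
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sim_gene_table(cfg)
    samples <- sim_samples(cfg, "L")
    sim_generate(cfg, genes, samples, "cg", "ex", "meth27k")
  })
}

#' Simulate an independent second-platform dataset
#'
#' Mirrors a validation compendium profiled on a different array: a fresh set
#' of samples and fresh noise, a distinct probe universe, and a gene content
#' that shares exactly
#' \code{round(platform_overlap_fraction * n_genes)} genes with the base
#' dataset (drift genes are always among the shared genes, as a recurrent
#' aberration must be observable on both platforms).
#'
#' @param base Output of \code{\link{simulate_dataset}}.
#' @param cfg The \code{\link{sim_config}} for the second dataset; defaults
#'   and seed handling: the RNG stream is derived from \code{cfg$seed + 1e6}
#'   so the two datasets are independent but jointly reproducible.
#' @return Same shape as \code{\link{simulate_dataset}}; methylation probes
#'   carry platform \code{"meth450k"} and prefix \code{"cgB"}.
#' @export
simulate_second_platform <- function(base, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  base_genes <- unique(base$annotation$gene)
  drift <- base$truth$drift_genes
  with_seed(cfg$seed + 1000000L, {
    n_shared <- round(cfg$platform_overlap_fraction * cfg$n_genes)
    if (n_shared < length(drift))
      stop("platform overlap too small to carry all drift genes")
    shared <- c(drift,
                sample(setdiff(base_genes, drift), n_shared - length(drift)))
    fresh <- sprintf("H%05d", seq_len(cfg$n_genes - n_shared))
    gene_ids <- c(shared, fresh)
    ann <- base$annotation[!duplicated(base$annotation$gene), ]
    chromosome <- character(length(gene_ids))
    position <- integer(length(gene_ids))
    is_shared <- gene_ids %in% shared
    m <- match(gene_ids[is_shared], ann$gene)
    chromosome[is_shared] <- ann$chromosome[m]
    position[is_shared] <- ann$position[m]
    chromosome[!is_shared] <- sample(CHROMOSOMES, sum(!is_shared),
                                     replace = TRUE, prob = chrom_weights())
    position[!is_shared] <- seq_len(sum(!is_shared)) * 100000L + 50000L
    genes <- data.frame(gene = gene_ids, chromosome = chromosome,
                        position = position,
                        drift = gene_ids %in% drift,
                        unexpressed = FALSE, stringsAsFactors = FALSE)
    samples <- sim_samples(cfg, "M")
    sim_generate(cfg, genes, samples, "cgB", "exB", "meth450k")
  })
}

#' Construct a knockdown-vs-control FPKM table with planted DE genes
#'
#' Builds a two-replicate knockdown / two-replicate control expression table
#' (linear FPKM scale) in which exactly \code{n_de} genes satisfy the
#' differential-expression filter of \code{\link{de_filter}} (mean fold
#' change > 2 and both replicate folds > 1.5), while every other gene sits at
#' or just below one of the rule's boundaries. Used to validate the filter's
#' exactness.
#'
#' @param n_genes Total genes.
#' @param n_de Genes planted to pass (half down-, half up-regulated).
#' @param seed Integer seed.
#' @return A list with \code{kd} and \code{ctrl} (gene x 2 matrices),
#'   and \code{de_genes} (ids planted to pass).
#' @export
simulate_knockdown <- function(n_genes = 10000, n_de = 126, seed = 1L) {
  stopifnot(n_de <= n_genes)
  with_seed(seed, {
    gene <- sprintf("KG%05d", seq_len(n_genes))
    ctrl <- matrix(stats::runif(2 * n_genes, 8, 12), ncol = 2,
                   dimnames = list(gene, c("ctrl_1", "ctrl_2")))
    kd <- ctrl * matrix(stats::runif(2 * n_genes, 0.85, 1.15), ncol = 2)
    de <- sample(n_genes, n_de)
    n_down <- ceiling(n_de / 2)
    down <- de[seq_len(n_down)]; up <- de[-seq_len(n_down)]
    cm <- rowMeans(ctrl)
    # planted effects: clear 2x mean fold and 1.5x in each replicate
    kd[down, ] <- cm[down] / cbind(stats::runif(length(down), 3, 6),
                                   stats::runif(length(down), 3, 6))
    kd[up, ] <- cm[up] * cbind(stats::runif(length(up), 3, 6),
                               stats::runif(length(up), 3, 6))
    # boundary genes: mean fold just under 2, or one replicate fold under 1.5
    n_edge <- min(200L, n_genes - n_de)
    edge <- setdiff(seq_len(n_genes), de)[seq_len(n_edge)]
    half <- edge[seq_len(floor(n_edge / 2))]
    kd[half, ] <- cm[half] / 1.95
    rest <- setdiff(edge, half)
    kd[rest, 1] <- cm[rest] / 1.4
    kd[rest, 2] <- cm[rest] / 4
    dimnames(kd) <- list(gene, c("kd_1", "kd_2"))
    list(kd = kd, ctrl = ctrl, de_genes = gene[sort(de)])
  })
}
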