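#' Assign samples to low- and high-passage groups
#'
#' Two grouping designs are supported. The \code{strict} design contrasts
#' samples at passage 25 or below with samples at passage 50 or above,
#' excluding the gap in between; it is used when the compendium has enough
#' very-high-passage samples. The \code{permissive} design contrasts passage
#' <= 25 with everything above 25, for compendia lacking very-high-passage
#' samples.
#'
#' @param samples Sample table with \code{passage} and (optionally computed)
#'   \code{qc_pass}.
#' @param mode \code{"strict"} (low <= 25, high >= 50) or
#'   \code{"permissive"} (low <= 25, high > 25).
#' @param require_qc If \code{TRUE} (default) samples with
#'   \code{qc_pass == FALSE} are excluded; samples with unknown QC status are
#'   kept.
#' @return An object of class \code{"group_assignment"}: a data.frame with
#'   \code{sample_id}, \code{passage} and \code{label}
#'   (\code{low}/\code{high}/\code{excluded}), plus attributes \code{mode}
#'   and \code{counts}. Errors if either group ends up empty.
#' @export
assign_groups <- function(samples, mode = c("strict", "permissive"),
                          require_qc = TRUE) {
  mode <- match.arg(mode)
  keep <- if (require_qc) !isFALSE_vec(samples$qc_pass) else
    rep(TRUE, nrow(samples))
  p <- samples$passage
  label <- rep("excluded", nrow(samples))
  if (mode == "strict") {
    label[keep & p <= 25] <- "low"
    label[keep & p >= 50] <- "high"
  } else {
    label[keep & p <= 25] <- "low"
    label[keep & p > 25] <- "high"
  }
  counts <- c(low = sum(label == "low"), high = sum(label == "high"),
              excluded = sum(label == "excluded"))
  if (counts["low"] == 0 || counts["high"] == 0)
    stop("empty passage group under mode '", mode, "' (low=", counts["low"],
         ", high=", counts["high"], ")")
  out <- data.frame(sample_id = samples$sample_id, passage = p,
                    label = label, stringsAsFactors = FALSE)
  structure(out, mode = mode, counts = counts,
            class = c("group_assignment", "data.frame"))
}

isFALSE_vec <- function(x) !is.na(x) & x == FALSE

#' @export
print.group_assignment <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("passage groups (", attr(x, "mode"), " mode): ",
      counts["low"], " low, ", counts["high"], " high, ",
      counts["excluded"], " excluded\n", sep = "")
  invisible(x)
}

# Row-wise Pearson correlation of two matched matrices, NA pairs excluded.
row_cor <- function(A, B) {
  ok <- !is.na(A) & !is.na(B)
  A[!ok] <- NA; B[!ok] <- NA
  n <- rowSums(ok)
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  A0 <- A - ma; B0 <- B - mb
  A0[!ok] <- 0; B0[!ok] <- 0
  num <- rowSums(A0 * B0)
  den <- sqrt(rowSums(A0^2) * rowSums(B0^2))
  out <- num / den
  out[den == 0 | n < 3] <- NA_real_
  out
}

row_aggregate <- function(m, how) {
  if (how == "mean") rowMeans(m, na.rm = TRUE)
  else apply(m, 1, stats::median, na.rm = TRUE)
}

#' Screen probes for passage-dependent hypermethylation with silencing
#'
#' The core screen: for every gene-linked methylation probe it computes the
#' methylation difference between the high- and low-passage groups
#' (\eqn{\Delta\beta}), the expression fold change of the linked gene
#' (low-group aggregate of linear expression divided by the high-group
#' aggregate, so values above 1 mean downregulation at high passage), and
#' the Pearson correlation between methylation and expression across matched
#' samples. A probe is a candidate when \eqn{\Delta\beta} exceeds
#' \code{delta_beta_cutoff} \emph{and} the downregulation fold exceeds
#' \code{fold_cutoff} (both strictly). The opposite quadrant (hypomethylated
#' and upregulated) is reported but not flagged.
#'
#' By default \eqn{\Delta\beta} uses group means and the expression fold uses
#' the ratio of group medians of linearized (\eqn{2^x}) values; both
#' aggregates are configurable and agree on symmetric noise-free data.
#'
#' @param beta Filtered beta matrix (see \code{\link{filter_probes}}).
#' @param expr Filtered, floored expression matrix.
#' @param annotation Probe annotation covering both matrices.
#' @param groups A \code{\link{assign_groups}} result (or named low/high
#'   vector).
#' @param delta_beta_cutoff Methylation-difference cutoff, default 0.2.
#' @param fold_cutoff Expression-fold cutoff, default 1.5.
#' @param beta_aggregate \code{"mean"} (default) or \code{"median"}.
#' @param expr_aggregate \code{"median"} (default) or \code{"mean"}.
#' @param min_samples Minimum non-missing samples per group for a probe to
#'   be evaluable (default 3).
#' @return An object of class \code{"drift_screen"} with a \code{records}
#'   data.frame (one row per gene-linked methylation probe), the cutoffs,
#'   group counts, and candidate probe/gene counts. See
#'   \code{\link{candidate_gene_set}}, \code{plot.drift_screen}.
#' @export
drift_screen <- function(beta, expr, annotation, groups,
                         delta_beta_cutoff = 0.2, fold_cutoff = 1.5,
                         beta_aggregate = c("mean", "median"),
                         expr_aggregate = c("median", "mean"),
                         min_samples = 3) {
  beta_aggregate <- match.arg(beta_aggregate)
  expr_aggregate <- match.arg(expr_aggregate)
  labels <- group_labels(groups)
  low <- intersect(names(labels)[labels == "low"],
                   intersect(colnames(beta), colnames(expr)))
  high <- intersect(names(labels)[labels == "high"],
                    intersect(colnames(beta), colnames(expr)))
  if (length(low) == 0 || length(high) == 0)
    stop("no samples with both methylation and expression data in a group")

  gene_of <- stats::setNames(annotation$gene, annotation$probe_id)
  mprobe <- rownames(beta)[gene_of[rownames(beta)] != ""]
  mgene <- gene_of[mprobe]

  # one representative expression probe per gene: highest mean expression
  eprobes <- rownames(expr)
  egene <- gene_of[eprobes]
  emean <- rowMeans(unclass(expr)[, c(low, high), drop = FALSE], na.rm = TRUE)
  ord <- order(egene, -emean)
  rep_probe <- stats::setNames(eprobes[ord][!duplicated(egene[ord])],
                               egene[ord][!duplicated(egene[ord])])
  has_expr <- mgene %in% names(rep_probe)
  mprobe <- mprobe[has_expr]; mgene <- mgene[has_expr]

  B <- unclass(beta)[mprobe, , drop = FALSE]
  E <- unclass(expr)[rep_probe[mgene], , drop = FALSE]
  n_low <- rowSums(!is.na(B[, low, drop = FALSE]))
  n_high <- rowSums(!is.na(B[, high, drop = FALSE]))
  evaluable <- n_low >= min_samples & n_high >= min_samples

  delta_beta <- row_aggregate(B[, high, drop = FALSE], beta_aggregate) -
    row_aggregate(B[, low, drop = FALSE], beta_aggregate)
  lin <- 2^E
  expr_fold <- row_aggregate(lin[, low, drop = FALSE], expr_aggregate) /
    row_aggregate(lin[, high, drop = FALSE], expr_aggregate)
  both <- c(low, high)
  corr <- row_cor(B[, both, drop = FALSE], E[, both, drop = FALSE])

  candidate <- evaluable & delta_beta > delta_beta_cutoff &
    expr_fold > fold_cutoff
  hypo_up <- evaluable & delta_beta < -delta_beta_cutoff &
    expr_fold < 1 / fold_cutoff

  records <- data.frame(
    probe_id = mprobe, gene = unname(mgene),
    expr_probe = unname(rep_probe[mgene]),
    delta_beta = unname(delta_beta), expr_fold = unname(expr_fold),
    meth_expr_corr = unname(corr),
    n_low = unname(n_low), n_high = unname(n_high),
    evaluable = unname(evaluable),
    candidate = unname(candidate), hypo_up = unname(hypo_up),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    records = records,
    cutoffs = list(delta_beta = delta_beta_cutoff, fold = fold_cutoff,
                   beta_aggregate = beta_aggregate,
                   expr_aggregate = expr_aggregate,
                   min_samples = min_samples),
    group_counts = c(low = length(low), high = length(high)),
    n_candidate_probes = sum(candidate),
    candidate_genes = sort(unique(mgene[candidate]))
  ), class = "drift_screen")
}

#' Candidate genes of a screen
#'
#' A gene is a candidate when at least one of its methylation probes passes
#' the screen; several candidate probes on one gene collapse to one gene.
#'
#' @param x A \code{\link{drift_screen}} result (or its \code{records}
#'   data.frame).
#' @return Sorted character vector of candidate gene symbols.
#' @export
candidate_gene_set <- function(x) {
  records <- if (inherits(x, "drift_screen")) x$records else x
  sort(unique(records$gene[records$candidate]))
}

#' @export
print.drift_screen <- function(x, ...) {
  cat("methylation/expression drift screen\n")
  cat("  groups: ", x$group_counts["low"], " low / ",
      x$group_counts["high"], " high passage samples\n", sep = "")
  cat("  cutoffs: delta-beta > ", x$cutoffs$delta_beta, ", fold > ",
      x$cutoffs$fold, "\n", sep = "")
  cat("  ", nrow(x$records), " gene-linked probes screened (",
      sum(!x$records$evaluable), " unevaluable)\n", sep = "")
  cat("  ", x$n_candidate_probes,
      " hypermethylated/downregulated candidate probes, corresponding to ",
      length(x$candidate_genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
summary.drift_screen <- function(object, ...) {
  r <- object$records
  out <- list(
    n_probes = nrow(r),
    n_unevaluable = sum(!r$evaluable),
    n_candidate_probes = object$n_candidate_probes,
    candidate_genes = object$candidate_genes,
    n_hypo_up_probes = sum(r$hypo_up),
    median_corr_candidates =
      stats::median(r$meth_expr_corr[r$candidate], na.rm = TRUE),
    cutoffs = object$cutoffs,
    group_counts = object$group_counts)
  class(out) <- "summary.drift_screen"
  out
}

#' @export
print.summary.drift_screen <- function(x, ...) {
  cat(x$n_candidate_probes, "candidate probes /",
      length(x$candidate_genes), "candidate genes out of", x$n_probes,
      "screened probes\n")
  if (length(x$candidate_genes) > 0)
    cat("genes:", paste(x$candidate_genes, collapse = ", "), "\n")
  cat("median methylation-expression correlation among candidates:",
      format(x$median_corr_candidates, digits = 3), "\n")
  invisible(x)
}

#' Scatter plot of the screen (methylation difference vs expression fold)
#'
#' @param x A \code{\link{drift_screen}} result.
#' @param ... Passed to \code{plot}.
#' @export
plot.drift_screen <- function(x, ...) {
  r <- x$records[x$records$evaluable, ]
  graphics::plot(log2(r$expr_fold), r$delta_beta,
                 pch = 20, cex = 0.4,
                 col = ifelse(r$candidate, "red", "grey40"),
                 xlab = "log2 fold downregulation (low/high)",
                 ylab = "delta beta (high - low)", ...)
  graphics::abline(h = c(-1, 1) * x$cutoffs$delta_beta, col = "red",
                   lty = 2)
  graphics::abline(v = c(-1, 1) * log2(x$cutoffs$fold), col = "red",
                   lty = 2)
  invisible(x)
}

#' Validate candidate genes on an expression compendium
#'
#' Tests, per expression probe of each candidate gene, whether expression is
#' reduced in the high-passage group using a two-sided Wilcoxon rank-sum
#' test, with Benjamini-Hochberg FDR correction across all tested probes. A
#' gene validates when at least one of its probes has \eqn{q <} \code{alpha}
#' together with a lower high-group mean.
#'
#' @param expr Log2 expression matrix of the compendium.
#' @param samples Sample table for the compendium (passage required).
#' @param genes Character vector of candidate genes to test.
#' @param annotation Probe annotation for the compendium's probes.
#' @param mode Grouping design, default \code{"permissive"} (low <= 25 vs
#'   > 25), the design used when very-high-passage samples are scarce.
#' @param alpha FDR level, default 0.05.
#' @param min_samples Minimum group size per probe, default 3.
#' @return A list with \code{probes} (per-probe statistic table: p, q,
#'   group means, direction) and \code{genes} (per-gene validated flag).
#' @export
validate_expression_compendium <- function(expr, samples, genes, annotation,
                                           mode = "permissive", alpha = 0.05,
                                           min_samples = 3) {
  groups <- assign_groups(samples, mode = mode)
  labels <- group_labels(groups)
  low <- intersect(names(labels)[labels == "low"], colnames(expr))
  high <- intersect(names(labels)[labels == "high"], colnames(expr))
  gene_of <- stats::setNames(annotation$gene, annotation$probe_id)
  probes <- rownames(expr)[gene_of[rownames(expr)] %in% genes]
  if (length(probes) == 0)
    stop("no expression probes found for the requested genes")
  res <- lapply(probes, function(pr) {
    lo <- unclass(expr)[pr, low]; hi <- unclass(expr)[pr, high]
    lo <- lo[!is.na(lo)]; hi <- hi[!is.na(hi)]
    if (length(lo) < min_samples || length(hi) < min_samples)
      return(data.frame(probe_id = pr, gene = unname(gene_of[pr]),
                        mean_low = NA_real_, mean_high = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    p <- suppressWarnings(
      stats::wilcox.test(lo, hi, alternative = "two.sided")$p.value)
    data.frame(probe_id = pr, gene = unname(gene_of[pr]),
               mean_low = mean(lo), mean_high = mean(hi), p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$reduced_in_high <- !is.na(tab$p) & tab$q < alpha &
    tab$mean_high < tab$mean_low
  gene_tab <- data.frame(
    gene = genes,
    validated = vapply(genes, function(g)
      any(tab$reduced_in_high[tab$gene == g]), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(probes = tab, genes = gene_tab,
       params = list(mode = mode, alpha = alpha,
                     n_low = length(low), n_high = length(high)))
}
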