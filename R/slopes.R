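#' Per-probe linear regression of methylation against passage number
#'
#' For every methylation probe, fits ordinary least squares of beta values on
#' passage number and extracts the slope, an estimate of the methylation
#' change per passage in culture: a slope near zero means a stable probe,
#' positive means progressive methylation gain. Missing beta values are
#' excluded pairwise.
#'
#' @param beta Beta matrix (probes x samples).
#' @param samples Sample table supplying each sample's passage.
#' @param annotation Probe annotation (gene link and CpG-island flag are
#'   carried into the result; probes absent from the annotation are
#'   dropped).
#' @return An object of class \code{"drift_slopes"}: a list with
#'   \code{records} (probe_id, gene, slope, intercept, n_samples,
#'   in_cpg_island). Errors when fewer than 3 distinct passage values are
#'   present. Probes with fewer than 3 usable samples, or fewer than 2
#'   distinct passages after missing-value removal, get \code{NA} slopes.
#' @export
fit_methylation_slopes <- function(beta, samples, annotation) {
  p <- samples$passage[match(colnames(beta), samples$sample_id)]
  if (anyNA(p))
    stop("samples missing from the sample table: ",
         paste(utils::head(colnames(beta)[is.na(p)], 5), collapse = ", "))
  if (length(unique(p)) < 3)
    stop("at least 3 distinct passage values are required (got ",
         length(unique(p)), ")")
  keep <- rownames(beta) %in% annotation$probe_id
  B <- unclass(beta)[keep, , drop = FALSE]
  ok <- !is.na(B)
  n <- rowSums(ok)
  P <- matrix(p, nrow(B), ncol(B), byrow = TRUE)
  Sx <- rowSums(P * ok)
  Sy <- rowSums(B, na.rm = TRUE)
  Sxx <- rowSums(P * P * ok)
  Sxy <- rowSums(B * P, na.rm = TRUE)
  den <- n * Sxx - Sx^2
  slope <- (n * Sxy - Sx * Sy) / den
  intercept <- (Sy - slope * Sx) / n
  bad <- n < 3 | den <= 0
  slope[bad] <- NA_real_; intercept[bad] <- NA_real_
  m <- match(rownames(B), annotation$probe_id)
  records <- data.frame(
    probe_id = rownames(B),
    gene = annotation$gene[m],
    slope = unname(slope), intercept = unname(intercept),
    n_samples = as.integer(unname(n)),
    in_cpg_island = annotation$in_cpg_island[m],
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(records = records,
                 passages = stats::setNames(p, colnames(beta))),
            class = "drift_slopes")
}

#' @export
print.drift_slopes <- function(x, ...) {
  s <- x$records$slope
  cat("methylation-vs-passage regression:", nrow(x$records), "probes,",
      sum(!is.na(s)), "fitted\n")
  cat("  slope quartiles (beta/passage):",
      paste(format(stats::quantile(s, c(.25, .5, .75), na.rm = TRUE),
                   digits = 3), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.drift_slopes <- function(object, ...) {
  r <- object$records
  m <- cbind(intercept = r$intercept, slope = r$slope)
  rownames(m) <- r$probe_id
  m
}

#' Rank probes by methylation slope genome-wide
#'
#' Ranks all gene-linked probes by descending slope (rank 1 = strongest
#' methylation gain per passage). Percentiles share ties (competition
#' ranking); the deterministic per-probe order breaks ties by probe id. When
#' candidate genes are supplied, each of their probes is flagged for
#' membership in the top \code{top_fraction} of the distribution and an
#' island vs open-sea contrast table is emitted (island probes of drifting
#' genes are expected near the top; their open-sea probes to be relatively
#' stable).
#'
#' @param x A \code{\link{fit_methylation_slopes}} result.
#' @param candidate_genes Optional character vector of genes to summarize.
#' @param top_fraction Fraction defining "top-ranked", default 0.01 (top 1\%).
#' @return A list with \code{records} (slope records plus \code{rank},
#'   \code{percentile}, \code{top_flag}), \code{universe_size}, and, when
#'   candidates are given, \code{candidate_summary} (per island status:
#'   probes, mean slope, top-fraction membership).
#' @export
rank_slopes <- function(x, candidate_genes = NULL, top_fraction = 0.01) {
  stopifnot(inherits(x, "drift_slopes"))
  r <- x$records[x$records$gene != "" & !is.na(x$records$slope), ]
  if (nrow(r) == 0) stop("no gene-linked probes with fitted slopes")
  ord <- order(-r$slope, r$probe_id)
  r <- r[ord, ]
  r$rank <- seq_len(nrow(r))
  # tied slopes share the (conservative) worst position
  shared <- rank(-r$slope, ties.method = "max")
  r$percentile <- 100 * shared / nrow(r)
  r$top_flag <- r$percentile <= 100 * top_fraction
  out <- list(records = r, universe_size = nrow(r),
              top_fraction = top_fraction)
  if (!is.null(candidate_genes)) {
    cand <- r[r$gene %in% candidate_genes, ]
    out$candidate_summary <- do.call(rbind, lapply(
      split(cand, cand$in_cpg_island), function(d)
        data.frame(in_cpg_island = d$in_cpg_island[1],
                   n_probes = nrow(d),
                   mean_slope = mean(d$slope),
                   n_top = sum(d$top_flag),
                   frac_top = mean(d$top_flag))))
    rownames(out$candidate_summary) <- NULL
  }
  out
}

#' Rank genes and probes by cross-sample variability
#'
#' Genes whose methylation state drifts during culture are expected to be
#' among the most variable in both expression and methylation. Computes the
#' unbiased sample variance across samples for every expression probe (log2
#' scale) and every CpG-island methylation probe (raw beta scale), ranks them
#' in descending order, and tests the enrichment of a candidate gene set in
#' the top decile of each ranking with a one-sided hypergeometric test (see
#' \code{\link{intersect_candidates}}).
#'
#' @param expr Log2 expression matrix.
#' @param beta Beta matrix.
#' @param annotation Probe annotation for both.
#' @param candidate_genes Optional gene set to test for enrichment.
#' @param island_only Restrict methylation variance to CpG-island probes
#'   (default \code{TRUE}).
#' @param top_fraction Fraction defining the "most variable" stratum,
#'   default 0.1.
#' @return A list with \code{expression} and \code{methylation} rank tables
#'   (probe_id, gene, variance, rank, percentile) and, when candidates are
#'   given, \code{enrichment} (per data kind, an
#'   \code{\link{intersect_candidates}} result over the gene universe of
#'   that ranking).
#' @export
variability_ranking <- function(expr, beta, annotation,
                                candidate_genes = NULL, island_only = TRUE,
                                top_fraction = 0.1) {
  if (ncol(expr) < 3 || ncol(beta) < 3)
    stop("at least 3 samples are required for a variance ranking")
  gene_of <- stats::setNames(annotation$gene, annotation$probe_id)
  island_of <- stats::setNames(annotation$in_cpg_island, annotation$probe_id)

  rank_table <- function(m, probes) {
    v <- apply(unclass(m)[probes, , drop = FALSE], 1, stats::var,
               na.rm = TRUE)
    ord <- order(-v, probes)
    d <- data.frame(probe_id = probes[ord],
                    gene = unname(gene_of[probes[ord]]),
                    variance = unname(v[ord]),
                    stringsAsFactors = FALSE, row.names = NULL)
    d$rank <- seq_len(nrow(d))
    d$percentile <- 100 * rank(-d$variance, ties.method = "max") / nrow(d)
    d
  }
  e_tab <- rank_table(expr, rownames(expr))
  m_probes <- rownames(beta)
  if (island_only) m_probes <- m_probes[island_of[m_probes] %in% TRUE]
  m_tab <- rank_table(beta, m_probes)

  out <- list(expression = e_tab, methylation = m_tab,
              top_fraction = top_fraction)
  if (!is.null(candidate_genes)) {
    enrich <- function(tab) {
      genes <- unique(tab$gene[tab$gene != ""])
      top <- unique(tab$gene[tab$percentile <= 100 * top_fraction &
                               tab$gene != ""])
      intersect_candidates(intersect(candidate_genes, genes), top,
                           universe = length(genes))
    }
    out$enrichment <- list(expression = enrich(e_tab),
                           methylation = enrich(m_tab))
  }
  out
}
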