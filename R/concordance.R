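#' Cross-dataset candidate overlap with hypergeometric significance
#'
#' Intersects two candidate gene sets and computes the upper-tail
#' hypergeometric probability of observing at least the realized overlap by
#' chance: \eqn{P(X \ge k)} for \eqn{X \sim}
#' Hypergeometric(universe, |a|, |b|). The tail is evaluated in log space
#' (\code{phyper(log.p = TRUE)}) so that overlaps of genome-scale screens,
#' whose probabilities can be far below double-precision underflow on the
#' linear scale, are still reported exactly via \code{log10_p}.
#'
#' The universe must be supplied by the caller: the principled choice is the
#' number of genes evaluable in \emph{both} datasets after filtering.
#'
#' @param a,b Character vectors (candidate gene sets).
#' @param universe Size of the gene universe both sets were drawn from.
#' @return An object of class \code{"overlap_result"}: list with set sizes,
#'   the overlapping genes, \code{p_value} and \code{log10_p}.
#' @examples
#' intersect_candidates(letters[1:5], letters[1:5], universe = 20)
#' @export
intersect_candidates <- function(a, b, universe) {
  a <- unique(a); b <- unique(b)
  if (universe < length(union(a, b)))
    stop("universe (", universe, ") smaller than the union of the sets (",
         length(union(a, b)), ")")
  ov <- intersect(a, b)
  k <- length(ov)
  log_p <- stats::phyper(k - 1, length(a), universe - length(a), length(b),
                         lower.tail = FALSE, log.p = TRUE)
  structure(list(set_a_size = length(a), set_b_size = length(b),
                 universe_size = universe, overlap = sort(ov),
                 overlap_size = k,
                 p_value = exp(log_p), log10_p = log_p / log(10)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("gene-set overlap: ", x$overlap_size, " of ", x$set_a_size, " x ",
      x$set_b_size, " (universe ", x$universe_size, ")\n", sep = "")
  cat("  upper-tail hypergeometric p = ", format(x$p_value, digits = 4),
      " (log10 p = ", format(x$log10_p, digits = 4), ")\n", sep = "")
  if (x$overlap_size > 0 && x$overlap_size <= 25)
    cat("  genes:", paste(x$overlap, collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of samples with two main branches
#'
#' Clusters samples by their methylation or expression profiles using
#' complete linkage on either correlation distance (1 - Pearson r, the
#' default) or Euclidean distance. The two main branches are the two
#' children of the dendrogram root (a cut into exactly two clusters).
#'
#' @param m Probe-by-sample matrix.
#' @param distance \code{"pearson"} (distance = 1 - correlation) or
#'   \code{"euclidean"}.
#' @param feature_subset Optional vector of probe ids to cluster on (e.g. a
#'   top-variance subset); default all rows.
#' @return A list of class \code{"sample_clustering"}: \code{hclust} (the
#'   tree), \code{branches} (named integer vector, 1 or 2, per sample),
#'   \code{distance}.
#' @export
hierarchical_cluster <- function(m, distance = c("pearson", "euclidean"),
                                 feature_subset = NULL) {
  distance <- match.arg(distance)
  if (ncol(m) < 4) stop("at least 4 samples are required for clustering")
  x <- unclass(m)
  if (!is.null(feature_subset)) x <- x[feature_subset, , drop = FALSE]
  if (distance == "pearson") {
    sds <- apply(x, 2, stats::sd, na.rm = TRUE)
    if (any(sds == 0, na.rm = TRUE))
      stop("constant profile under pearson distance for sample(s): ",
           paste(colnames(x)[which(sds == 0)], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(x, use = "pairwise.complete.obs"))
  } else {
    d <- stats::dist(t(x), method = "euclidean")
  }
  hc <- stats::hclust(d, method = "complete")
  branches <- stats::cutree(hc, k = 2)
  structure(list(hclust = hc, branches = branches, distance = distance),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("complete-linkage clustering (", x$distance, " distance) of ",
      length(x$branches), " samples; main branches: ",
      sum(x$branches == 1), " / ", sum(x$branches == 2), "\n", sep = "")
  invisible(x)
}

#' Export a sample dendrogram as newick
#'
#' @param clustering A \code{\link{hierarchical_cluster}} result.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Test passage composition of the two main branches
#'
#' Builds the 2x2 table of branch membership against passage group and tests
#' it with a two-tailed Fisher's exact test (sum of the probabilities of all
#' tables, with the observed margins, whose probability does not exceed the
#' observed table's). A dendrogram that separates low- from high-passage
#' samples yields a small p.
#'
#' @param clustering A \code{\link{hierarchical_cluster}} result, or a named
#'   branch vector (values 1/2).
#' @param groups A \code{\link{assign_groups}} result (or named low/high
#'   vector) covering every clustered sample.
#' @param data_kind Label recorded in the result (\code{"expression"} or
#'   \code{"methylation"}).
#' @return An object of class \code{"cluster_test"}: the 2x2
#'   \code{branch_counts} table (branch x group) and \code{fisher_p}. If all
#'   samples fall in one passage group the test is degenerate: p is reported
#'   as 1 with a warning.
#' @export
branch_composition_test <- function(clustering, groups,
                                    data_kind = c("expression",
                                                  "methylation")) {
  data_kind <- match.arg(data_kind)
  branches <- if (inherits(clustering, "sample_clustering"))
    clustering$branches else clustering
  labels <- group_labels_lenient(groups)
  ids <- names(branches)
  if (!all(ids %in% names(labels)))
    stop("clustered sample(s) without a group label: ",
         paste(utils::head(setdiff(ids, names(labels)), 5), collapse = ", "))
  lab <- factor(labels[ids], levels = c("low", "high"))
  br <- factor(branches, levels = c(1, 2))
  tab <- table(branch = br, group = lab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in branch x group table; p reported as 1",
            call. = FALSE)
    p <- 1
  } else {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  structure(list(data_kind = data_kind,
                 distance = if (inherits(clustering, "sample_clustering"))
                   clustering$distance else NA_character_,
                 linkage = "complete",
                 branch_counts = tab, fisher_p = p),
            class = "cluster_test")
}

# like group_labels() but tolerates a single-group degenerate assignment
group_labels_lenient <- function(groups) {
  if (inherits(groups, "group_assignment")) {
    lab <- stats::setNames(groups$label, groups$sample_id)
  } else {
    lab <- groups
    if (is.null(lab) || is.null(names(lab)))
      stop("group assignment must be named by sample id")
  }
  lab[lab %in% c("low", "high")]
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("branch composition (", x$data_kind, ", ", x$linkage, " linkage):\n",
      sep = "")
  print(x$branch_counts)
  cat("two-tailed Fisher exact p =", format(x$fisher_p, digits = 4), "\n")
  invisible(x)
}

#' Clustering and branch tests within sample strata
#'
#' Repeats \code{\link{hierarchical_cluster}} +
#' \code{\link{branch_composition_test}} within each stratum (e.g. per sex,
#' to check that passage-driven clustering is not a sex artifact). Strata
#' with fewer than 4 samples are skipped with a warning.
#'
#' @param m Probe-by-sample matrix.
#' @param samples Sample table covering the matrix columns.
#' @param groups A \code{\link{assign_groups}} result.
#' @param stratify_by \code{"sex"} or \code{"none"} (plain clustering).
#' @param distance Passed to \code{\link{hierarchical_cluster}}.
#' @param data_kind Passed to \code{\link{branch_composition_test}}.
#' @return Named list of per-stratum lists, each with \code{clustering} and
#'   \code{test}.
#' @export
stratified_clustering <- function(m, samples, groups,
                                  stratify_by = c("sex", "none"),
                                  distance = "pearson",
                                  data_kind = "expression") {
  stratify_by <- match.arg(stratify_by)
  strata <- if (stratify_by == "none")
    list(all = colnames(m))
  else
    split(samples$sample_id, samples$sex)[
      unique(samples$sex[match(colnames(m), samples$sample_id)])]
  out <- list()
  for (s in names(strata)) {
    ids <- intersect(strata[[s]], colnames(m))
    if (length(ids) < 4) {
      warning("stratum '", s, "' has ", length(ids),
              " samples (<4); skipped", call. = FALSE)
      next
    }
    cl <- hierarchical_cluster(m[, ids, drop = FALSE], distance = distance)
    out[[s]] <- list(clustering = cl,
                     test = branch_composition_test(cl, groups,
                                                    data_kind = data_kind))
  }
  out
}
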