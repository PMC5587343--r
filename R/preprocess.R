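#' Raise low expression values to a fixed floor
#'
#' Expression values below the floor are raised to the floor to suppress
#' noise from non-expressed genes; values at or above the floor are left
#' untouched. For microarray data the floor is on the log2 scale; for
#' RNA-seq FPKM tables use \code{scale = "linear"} (the conventional FPKM
#' floor is 0.5).
#'
#' @param m Numeric expression matrix.
#' @param floor Scalar floor value.
#' @param scale \code{"log2"} (default) or \code{"linear"}; informational
#'   only, both apply the same elementwise maximum.
#' @return The floored matrix, with the floor recorded in the
#'   \code{"floor"} attribute. Downstream, a value equal to the floor is
#'   treated as "unexpressed".
#' @export
apply_expression_floor <- function(m, floor, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(floor), length(floor) == 1L, is.finite(floor))
  m[!is.na(m) & m < floor] <- floor
  attr(m, "floor") <- floor
  attr(m, "floor_scale") <- scale
  m
}

#' Range-scale beta values to control samples
#'
#' Rescales each probe's beta values so that the unmethylated control maps to
#' 0 and the fully methylated control to 1:
#' \deqn{\beta' = (\beta - u) / (m - u)}
#' clipped to \eqn{[0,1]}. If a half-methylated control is supplied it is
#' scaled alongside and its distance from 0.5 is reported (as an attribute
#' and a message), but a deviation never fails the call.
#'
#' @param m Beta matrix (probes x samples).
#' @param unmethylated,fully_methylated Per-probe vectors (named by probe or
#'   in row order) or scalars.
#' @param half_methylated Optional per-probe vector or scalar; check only.
#' @param min_dynamic_range Probes whose control range
#'   \code{fully_methylated - unmethylated} falls below this are flagged
#'   unusable: their values are set to \code{NA} and their ids recorded in
#'   the \code{"unusable_probes"} attribute.
#' @param half_tolerance Tolerance used when reporting how far the scaled
#'   half-methylated control sits from 0.5.
#' @return Rescaled beta matrix with attributes \code{"unusable_probes"} and
#'   (when a half-methylated control is given) \code{"half_scaled"} /
#'   \code{"half_within_tolerance"}.
#' @export
range_scale_betas <- function(m, unmethylated, fully_methylated,
                              half_methylated = NULL,
                              min_dynamic_range = 0.2,
                              half_tolerance = 0.1) {
  n <- nrow(m)
  u <- rep_len(unmethylated, n)
  f <- rep_len(fully_methylated, n)
  if (any(u >= f))
    stop("unmethylated control must be below the fully methylated control ",
         "for every probe")
  rng <- f - u
  unusable <- rng < min_dynamic_range
  scaled <- (unclass(m) - u) / rng
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  scaled[unusable, ] <- NA_real_
  out <- as_beta_matrix(scaled)
  attr(out, "unusable_probes") <- rownames(m)[unusable]
  if (!is.null(half_methylated)) {
    h <- (rep_len(half_methylated, n) - u) / rng
    attr(out, "half_scaled") <- h
    ok <- abs(h - 0.5) <= half_tolerance
    attr(out, "half_within_tolerance") <- ok
    if (!all(ok[!unusable]))
      message(sum(!ok[!unusable]),
              " probe(s) have half-methylated controls more than ",
              half_tolerance, " from 0.5 after scaling")
  }
  out
}

#' Filter probes before the methylation/expression screen
#'
#' Applies the two pre-screen filters: (1) probes on the sex chromosomes are
#' discarded; (2) a gene is dropped when it is unexpressed (at the expression
#' floor) in more than \code{max_unexpressed_fraction} of the samples in
#' \emph{both} passage groups. Methylation probes whose gene survives in the
#' expression data are kept. Additionally, methylation probes with more than
#' 50\% missing beta values in either group are dropped.
#'
#' @param beta Beta matrix.
#' @param expr Expression matrix (floored; see
#'   \code{\link{apply_expression_floor}}).
#' @param annotation Probe annotation covering both matrices.
#' @param groups A group assignment from \code{\link{assign_groups}}, or a
#'   named character vector mapping sample id to \code{"low"}/\code{"high"}.
#' @param max_unexpressed_fraction Drop threshold, default 0.80.
#' @param max_missing_fraction Per-group missing-beta tolerance, default 0.5.
#' @return A list with elements \code{beta}, \code{expr} (filtered matrices)
#'   and \code{log} (a named list of dropped counts).
#' @export
filter_probes <- function(beta, expr, annotation, groups,
                          max_unexpressed_fraction = 0.80,
                          max_missing_fraction = 0.5) {
  labels <- group_labels(groups)
  low <- names(labels)[labels == "low"]
  high <- names(labels)[labels == "high"]
  low_e <- intersect(low, colnames(expr))
  high_e <- intersect(high, colnames(expr))
  if (length(low_e) == 0 || length(high_e) == 0)
    stop("each passage group must contain at least one sample present in ",
         "the expression matrix")
  fl <- attr(expr, "floor")
  if (is.null(fl))
    stop("expression matrix has no recorded floor; run apply_expression_floor first")
  ann <- annotation
  autosomal <- ann$probe_id[!(ann$chromosome %in% c("X", "Y"))]
  n_beta0 <- nrow(beta); n_expr0 <- nrow(expr)
  beta <- beta[rownames(beta) %in% autosomal, , drop = FALSE]
  expr <- expr[rownames(expr) %in% autosomal, , drop = FALSE]
  dropped_sex <- c(beta = n_beta0 - nrow(beta), expr = n_expr0 - nrow(expr))

  at_floor <- !is.na(expr) & expr <= fl
  frac_low <- rowMeans(at_floor[, low_e, drop = FALSE])
  frac_high <- rowMeans(at_floor[, high_e, drop = FALSE])
  unexpressed <- frac_low > max_unexpressed_fraction &
    frac_high > max_unexpressed_fraction
  gene_of <- stats::setNames(ann$gene, ann$probe_id)
  dropped_genes <- setdiff(unique(gene_of[rownames(expr)[unexpressed]]), "")
  keep_expr <- !unexpressed
  expr_f <- expr[keep_expr, , drop = FALSE]
  beta_gene <- gene_of[rownames(beta)]
  beta_keep <- !(beta_gene %in% dropped_genes)
  beta_f <- beta[beta_keep, , drop = FALSE]

  low_b <- intersect(low, colnames(beta_f))
  high_b <- intersect(high, colnames(beta_f))
  miss_low <- rowMeans(is.na(beta_f[, low_b, drop = FALSE]))
  miss_high <- rowMeans(is.na(beta_f[, high_b, drop = FALSE]))
  beta_ok <- miss_low <= max_missing_fraction & miss_high <= max_missing_fraction
  beta_f <- beta_f[beta_ok, , drop = FALSE]

  list(
    beta = as_beta_matrix(unclass(beta_f)),
    expr = as_expr_matrix(unclass(expr_f), floor = fl),
    log = list(
      dropped_sex_chromosome = as.list(dropped_sex),
      dropped_unexpressed_genes = length(dropped_genes),
      dropped_unexpressed_expr_probes = sum(unexpressed),
      dropped_missing_beta_probes = sum(!beta_ok),
      retained_beta_probes = nrow(beta_f),
      retained_expr_probes = nrow(expr_f)
    )
  )
}

# Accept either an assign_groups() result or a named low/high vector.
group_labels <- function(groups) {
  if (inherits(groups, "group_assignment")) {
    lab <- groups$label
    names(lab) <- groups$sample_id
    lab <- lab[lab %in% c("low", "high")]
  } else {
    lab <- groups
    if (is.null(names(lab)))
      stop("group assignment must be named by sample id")
    lab <- lab[lab %in% c("low", "high")]
  }
  if (!any(lab == "low") || !any(lab == "high"))
    stop("both a 'low' and a 'high' passage group are required")
  lab
}
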