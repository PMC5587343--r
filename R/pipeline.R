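#' Run the full drift-screen pipeline from a declarative config
#'
#' Orchestrates simulate (or load) -> e-karyotype QC -> group assignment ->
#' probe filtering -> methylation/expression screen -> slope fitting and
#' ranking -> variability ranking -> clustering with branch-composition
#' tests -> second-platform screen and candidate intersection -> expression
#' compendium validation. Every stage's parameters and headline counts are
#' recorded in a consolidated report; identical config and seed give an
#' identical report.
#'
#' @param config A named list (or path to a YAML file) with any of:
#'   \describe{
#'     \item{simulate}{List of \code{\link{sim_config}} arguments, or
#'       \code{TRUE} for defaults. Mutually exclusive with \code{inputs}.}
#'     \item{inputs}{List of file paths: \code{beta}, \code{expr},
#'       \code{samples}, \code{annotation} (TSV, see
#'       \code{\link{read_matrix}}).}
#'     \item{group_mode}{\code{"strict"} (default) or \code{"permissive"}.}
#'     \item{delta_beta_cutoff, fold_cutoff}{Screen cutoffs (0.2, 1.5).}
#'     \item{expr_floor}{Log2 expression floor for loaded data.}
#'     \item{qc}{List: \code{window_genes}, \code{call_threshold},
#'       \code{noise_threshold}.}
#'     \item{fdr_alpha}{FDR level for the compendium validation (0.05).}
#'     \item{second_platform}{Logical: run the cross-platform concordance
#'       stage (simulated data only; default \code{TRUE}).}
#'     \item{seed}{Root seed; per-stage streams are derived from it.}
#'   }
#' @param out_dir Optional directory; when given, the report
#'   (\code{report.json}), screen records, slope records and candidate lists
#'   are written there.
#' @return A list of class \code{"drift_pipeline"}: stage results
#'   (\code{data}, \code{qc}, \code{screen}, \code{slopes}, \code{ranking},
#'   \code{variability}, \code{clustering}, \code{concordance},
#'   \code{validation}) plus \code{report}.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    simulate = TRUE, inputs = NULL, group_mode = "strict",
    delta_beta_cutoff = 0.2, fold_cutoff = 1.5, expr_floor = 4,
    qc = list(window_genes = 100, call_threshold = 0.3,
              noise_threshold = 0.8),
    fdr_alpha = 0.05, second_platform = TRUE, seed = 1L
  ), config)
  stopifnot(cfg$delta_beta_cutoff > 0, cfg$fold_cutoff > 0,
            cfg$fdr_alpha > 0)
  report <- list(parameters = cfg[setdiff(names(cfg), "inputs")],
                 stages = list())

  stage <- "load"
  result <- tryCatch({
    if (!is.null(cfg$inputs)) {
      for (f in unlist(cfg$inputs))
        if (!file.exists(f)) stop("input file not found: ", f)
      samples <- read_sample_table(cfg$inputs$samples)
      annotation <- read_probe_annotation(cfg$inputs$annotation)
      beta <- read_matrix(cfg$inputs$beta, "beta", annotation, samples)
      expr <- apply_expression_floor(
        read_matrix(cfg$inputs$expr, "expression", annotation, samples),
        cfg$expr_floor)
      data <- list(beta = beta, expr = expr, samples = samples,
                   annotation = annotation, truth = NULL)
    } else {
      sim_args <- if (isTRUE(cfg$simulate)) list() else cfg$simulate
      sim_args$seed <- cfg$seed
      scfg <- do.call(sim_config, sim_args)
      data <- simulate_dataset(scfg)
      data$sim_config <- scfg
    }
    report$stages$load <- list(
      n_beta_probes = nrow(data$beta), n_expr_probes = nrow(data$expr),
      n_samples = nrow(data$samples),
      beta_hash = matrix_hash(data$beta), expr_hash = matrix_hash(data$expr))

    stage <- "qc"
    scan <- suppressWarnings(
      ekaryotype_scan(data$expr, data$annotation,
                      window_genes = cfg$qc$window_genes,
                      call_threshold = cfg$qc$call_threshold,
                      noise_threshold = cfg$qc$noise_threshold))
    data$samples <- apply_qc(data$samples, scan)
    report$stages$qc <- c(scan$params,
                          list(n_failed = sum(!data$samples$qc_pass)))

    stage <- "groups"
    groups <- assign_groups(data$samples, mode = cfg$group_mode)
    report$stages$groups <- as.list(attr(groups, "counts"))

    stage <- "filter"
    filt <- filter_probes(data$beta, data$expr, data$annotation, groups)
    report$stages$filter <- filt$log

    stage <- "screen"
    screen <- drift_screen(filt$beta, filt$expr, data$annotation, groups,
                           delta_beta_cutoff = cfg$delta_beta_cutoff,
                           fold_cutoff = cfg$fold_cutoff)
    report$stages$screen <- list(
      cutoffs = screen$cutoffs[c("delta_beta", "fold")],
      n_probes = nrow(screen$records),
      n_candidate_probes = screen$n_candidate_probes,
      n_candidate_genes = length(screen$candidate_genes),
      candidate_genes = screen$candidate_genes)

    stage <- "slopes"
    slopes <- fit_methylation_slopes(filt$beta, data$samples,
                                     data$annotation)
    ranking <- rank_slopes(slopes,
                           candidate_genes = screen$candidate_genes)
    report$stages$slopes <- list(
      universe_size = ranking$universe_size,
      candidate_summary = ranking$candidate_summary)

    stage <- "variability"
    variability <- variability_ranking(filt$expr, filt$beta,
                                       data$annotation,
                                       candidate_genes =
                                         screen$candidate_genes)
    report$stages$variability <- list(
      expr_enrichment_p = variability$enrichment$expression$p_value,
      meth_enrichment_p = variability$enrichment$methylation$p_value)

    stage <- "clustering"
    grouped <- groups$sample_id[groups$label %in% c("low", "high")]
    clustering <- list(
      expression = hierarchical_cluster(
        filt$expr[, intersect(colnames(filt$expr), grouped), drop = FALSE],
        "pearson"),
      methylation = hierarchical_cluster(
        filt$beta[, intersect(colnames(filt$beta), grouped), drop = FALSE],
        "pearson"))
    cluster_tests <- list(
      expression = branch_composition_test(clustering$expression, groups,
                                           "expression"),
      methylation = branch_composition_test(clustering$methylation, groups,
                                            "methylation"))
    report$stages$clustering <- list(
      expression_fisher_p = cluster_tests$expression$fisher_p,
      methylation_fisher_p = cluster_tests$methylation$fisher_p)

    stage <- "concordance"
    concordance <- NULL
    if (isTRUE(cfg$second_platform) && !is.null(data$sim_config)) {
      d2 <- simulate_second_platform(data, data$sim_config)
      scan2 <- suppressWarnings(
        ekaryotype_scan(d2$expr, d2$annotation,
                        window_genes = cfg$qc$window_genes,
                        call_threshold = cfg$qc$call_threshold,
                        noise_threshold = cfg$qc$noise_threshold))
      d2$samples <- apply_qc(d2$samples, scan2)
      groups2 <- assign_groups(d2$samples, mode = cfg$group_mode)
      filt2 <- filter_probes(d2$beta, d2$expr, d2$annotation, groups2)
      screen2 <- drift_screen(filt2$beta, filt2$expr, d2$annotation,
                              groups2,
                              delta_beta_cutoff = cfg$delta_beta_cutoff,
                              fold_cutoff = cfg$fold_cutoff)
      gene_of1 <- unique(data$annotation$gene[
        data$annotation$probe_id %in% rownames(filt$beta)])
      gene_of2 <- unique(d2$annotation$gene[
        d2$annotation$probe_id %in% rownames(filt2$beta)])
      universe <- length(intersect(gene_of1, gene_of2))
      concordance <- list(
        screen2 = screen2,
        overlap = intersect_candidates(
          intersect(screen$candidate_genes, gene_of2),
          intersect(screen2$candidate_genes, gene_of1),
          universe = universe))
      report$stages$concordance <- list(
        universe = universe,
        universe_note = paste("universe = genes evaluable on both",
                              "platforms after filtering"),
        n_candidates_a = length(screen$candidate_genes),
        n_candidates_b = length(screen2$candidate_genes),
        overlap_size = concordance$overlap$overlap_size,
        log10_p = concordance$overlap$log10_p)
    }

    stage <- "validation"
    validation <- NULL
    if (length(screen$candidate_genes) > 0) {
      validation <- validate_expression_compendium(
        filt$expr, data$samples, screen$candidate_genes,
        data$annotation, mode = "permissive", alpha = cfg$fdr_alpha)
      report$stages$validation <- list(
        n_probes_tested = nrow(validation$probes),
        n_genes_validated = sum(validation$genes$validated))
    }

    list(data = data, qc = scan, groups = groups, filtered = filt,
         screen = screen, slopes = slopes, ranking = ranking,
         variability = variability, clustering = clustering,
         cluster_tests = cluster_tests, concordance = concordance,
         validation = validation)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result$report <- report

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_report(report, file.path(out_dir, "report.json"))
    utils::write.table(result$screen$records,
                       file.path(out_dir, "screen_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$ranking$records,
                       file.path(out_dir, "slope_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(result$screen$candidate_genes,
               file.path(out_dir, "candidate_genes.txt"))
  }
  class(result) <- "drift_pipeline"
  result
}

#' @export
print.drift_pipeline <- function(x, ...) {
  cat("drift-screen pipeline run\n")
  print(x$screen)
  if (!is.null(x$concordance)) {
    cat("cross-platform concordance:\n")
    print(x$concordance$overlap)
  }
  if (!is.null(x$validation))
    cat("compendium validation:", sum(x$validation$genes$validated), "of",
        nrow(x$validation$genes), "candidate genes validated\n")
  invisible(x)
}

# cheap content fingerprint for run reports (dims + value checksum)
matrix_hash <- function(m) {
  v <- unclass(m)
  sprintf("%dx%d:%.6e", nrow(v), ncol(v), sum(v, na.rm = TRUE))
}
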