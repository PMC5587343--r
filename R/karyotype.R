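#' Expression-based virtual karyotype scan
#'
#' Detects chromosome-scale expression biases indicative of large copy-number
#' aberrations (simplified e-karyotyping), and flags globally noisy
#' transcriptomes. Each gene is centered by its cross-sample median; within
#' each chromosome genes are ordered by position and a moving window of
#' \code{window_genes} genes (advancing one gene at a time) is averaged per
#' sample. A sample fails QC if any window's absolute mean reaches
#' \code{call_threshold}, or if the median absolute deviation of its centered
#' values reaches \code{noise_threshold}.
#'
#' A balanced trisomy shifts a whole chromosome by about \code{log2(1.5)}
#' (~0.585), comfortably above the default 0.3 call threshold, while random
#' expression noise averages out across a 100-gene window.
#'
#' @param expr Log2 expression matrix (probes x samples).
#' @param annotation Probe annotation with chromosome and position for the
#'   expression probes.
#' @param window_genes Moving-window width in genes (default 100).
#' @param call_threshold Absolute windowed log2 deviation calling an
#'   aberration (default 0.3).
#' @param noise_threshold Per-sample MAD of centered values above which the
#'   transcriptome is deemed too noisy (default 0.8).
#' @return An object of class \code{"ekaryo_scan"}: a list with
#'   \code{calls} (one row per sample x chromosome: extreme window score,
#'   its start index, aberrant flag), \code{sample_qc} (per-sample
#'   \code{qc_pass}, \code{global_noise}, number of aberrant chromosomes)
#'   and \code{params}. Chromosomes with fewer genes than the window are
#'   skipped with a warning.
#' @export
ekaryotype_scan <- function(expr, annotation, window_genes = 100,
                            call_threshold = 0.3, noise_threshold = 0.8) {
  if (ncol(expr) < 10)
    stop("at least 10 samples are required for a stable centering reference")
  ann <- annotation[match(rownames(expr), annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("expression probes missing from annotation")
  centered <- unclass(expr) - apply(unclass(expr), 1, stats::median, na.rm = TRUE)
  global_noise <- apply(centered, 2, stats::mad, na.rm = TRUE)

  calls <- list()
  for (ch in intersect(CHROMOSOMES, unique(ann$chromosome))) {
    i <- which(ann$chromosome == ch)
    i <- i[order(ann$position[i])]
    n <- length(i)
    if (n < window_genes) {
      warning("chromosome ", ch, " has ", n, " genes, fewer than the window (",
              window_genes, "); skipped", call. = FALSE)
      next
    }
    cs <- apply(centered[i, , drop = FALSE], 2, cumsum)
    w <- window_genes
    win <- (cs[w:n, , drop = FALSE] -
              rbind(0, cs[seq_len(n - w), , drop = FALSE])) / w
    extreme <- apply(win, 2, function(v) which.max(abs(v)))
    score <- win[cbind(extreme, seq_len(ncol(win)))]
    calls[[ch]] <- data.frame(
      sample_id = colnames(expr), chromosome = ch,
      window_start_index = extreme, window_score = score,
      aberrant = abs(score) >= call_threshold,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(calls) == 0) {
    calls <- data.frame(sample_id = character(0), chromosome = character(0),
                        window_start_index = integer(0),
                        window_score = numeric(0), aberrant = logical(0),
                        stringsAsFactors = FALSE)
    n_ab <- stats::setNames(rep(0L, ncol(expr)), colnames(expr))
  } else {
    calls <- do.call(rbind, calls)
    rownames(calls) <- NULL
    n_ab <- tapply(calls$aberrant, calls$sample_id, sum)[colnames(expr)]
  }
  sample_qc <- data.frame(
    sample_id = colnames(expr),
    global_noise = unname(global_noise),
    n_aberrant_chromosomes = unname(as.integer(n_ab)),
    qc_pass = unname(n_ab == 0 & global_noise < noise_threshold),
    stringsAsFactors = FALSE)
  structure(list(calls = calls, sample_qc = sample_qc,
                 params = list(window_genes = window_genes,
                               call_threshold = call_threshold,
                               noise_threshold = noise_threshold)),
            class = "ekaryo_scan")
}

#' @export
print.ekaryo_scan <- function(x, ...) {
  cat("e-karyotype scan:", nrow(x$sample_qc), "samples,",
      sum(!x$sample_qc$qc_pass), "failing QC\n")
  cat("  window:", x$params$window_genes, "genes; call threshold:",
      x$params$call_threshold, "log2; noise threshold:",
      x$params$noise_threshold, "\n")
  ab <- x$calls[x$calls$aberrant, , drop = FALSE]
  if (nrow(ab) > 0) {
    cat("  aberrant sample x chromosome calls:\n")
    print(ab, row.names = FALSE)
  }
  invisible(x)
}

#' Record QC results into a sample table
#'
#' @param samples Sample table.
#' @param scan An \code{\link{ekaryotype_scan}} result.
#' @return The sample table with \code{qc_pass} filled in; samples absent
#'   from the scan keep their previous value.
#' @export
apply_qc <- function(samples, scan) {
  stopifnot(inherits(scan, "ekaryo_scan"))
  m <- match(samples$sample_id, scan$sample_qc$sample_id)
  upd <- !is.na(m)
  samples$qc_pass[upd] <- scan$sample_qc$qc_pass[m[upd]]
  samples
}
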