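#' Read a probe-by-sample matrix from TSV
#'
#' Matrices are stored as tab-separated text with probe identifiers in the
#' first column (header cell \code{"probe_id"}) and sample identifiers in the
#' remaining header cells. Empty cells are read as missing (\code{NA}), never
#' as zero.
#'
#' @param path Path to a TSV file.
#' @param kind \code{"beta"} for methylation beta values (validated to lie in
#'   \eqn{[0,1]}) or \code{"expression"} for log2 expression values.
#' @param annotation Optional probe annotation (see
#'   \code{\link{read_probe_annotation}}); row labels are checked against it.
#' @param samples Optional sample table (see \code{\link{read_sample_table}});
#'   column labels are checked against it.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames, classed \code{"beta_matrix"} or \code{"expr_matrix"}.
#' @seealso \code{\link{write_matrix_tsv}} for the inverse operation.
#' @export
read_matrix <- function(path, kind = c("beta", "expression"),
                        annotation = NULL, samples = NULL) {
  kind <- match.arg(kind)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in '", path, "': expected 'probe_id' plus at least one sample column")
  if (header[1] != "probe_id")
    stop("malformed header in '", path, "': first header cell must be 'probe_id', got '",
         header[1], "'")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header of '", path, "': ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  raw <- utils::read.table(path, sep = "\t", header = TRUE, skip = 0L,
                           colClasses = c("character", rep("character", length(sample_ids))),
                           check.names = FALSE, quote = "", comment.char = "",
                           na.strings = c("", "NA"))
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids in '", path, "': ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell at probe '", probe_ids[bad[1, 1]], "', sample '",
         sample_ids[bad[1, 2]], "' in '", path, "'")
  dimnames(num) <- list(probe_ids, sample_ids)
  m <- if (kind == "beta") as_beta_matrix(num) else as_expr_matrix(num)
  if (!is.null(annotation)) {
    missing_probes <- setdiff(probe_ids, annotation$probe_id)
    if (length(missing_probes) > 0)
      stop("probes absent from annotation: ",
           paste(utils::head(missing_probes, 5), collapse = ", "))
  }
  if (!is.null(samples)) {
    missing_samples <- setdiff(sample_ids, samples$sample_id)
    if (length(missing_samples) > 0)
      stop("samples absent from sample table: ",
           paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  m
}

#' Write a probe-by-sample matrix to TSV
#'
#' Values are written with full precision (\code{format(..., digits = 17)})
#' so a read/write round trip is bit-exact; missing values become empty cells.
#'
#' @param m Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  chr <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    cells <- ifelse(is.na(v), "", vapply(v, format, "", digits = 17))
    paste(c(rownames(m)[i], cells), collapse = "\t")
  }, "")
  writeLines(chr, con)
  invisible(path)
}

as_beta_matrix <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  out <- x[!is.na(x) & (x < 0 | x > 1)]
  if (length(out) > 0)
    stop("beta value out of [0,1]: ", format(out[1]))
  class(x) <- c("beta_matrix", class(x))
  x
}

as_expr_matrix <- function(x, floor = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.null(floor)) attr(x, "floor") <- floor
  class(x) <- c("expr_matrix", class(x))
  x
}

#' Read the sample metadata table
#'
#' Expected TSV columns: \code{sample_id}, \code{cell_line}, \code{passage}
#' (non-negative integer), \code{sex} (\code{female}/\code{male}/
#' \code{unknown}), \code{cell_type} (\code{hESC}/\code{hiPSC}/\code{other})
#' and optionally \code{qc_pass} (logical).
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param df A data.frame to validate in place of reading a file.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "cell_line", "passage", "sex", "cell_type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(is.na(df$passage)) || any(df$passage < 0))
    stop("passage must be a non-negative integer for every sample")
  bad_sex <- setdiff(unique(df$sex), c("female", "male", "unknown"))
  if (length(bad_sex) > 0)
    stop("invalid sex values: ", paste(bad_sex, collapse = ", "))
  bad_ct <- setdiff(unique(df$cell_type), c("hESC", "hiPSC", "other"))
  if (length(bad_ct) > 0)
    stop("invalid cell_type values: ", paste(bad_ct, collapse = ", "))
  if (is.null(df$qc_pass)) df$qc_pass <- NA
  df
}

CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome names
#'
#' Accepts names with or without a \code{"chr"} prefix and returns bare names
#' (\code{"1"}..\code{"22"}, \code{"X"}, \code{"Y"}).
#'
#' @param chr Character vector of chromosome names.
#' @return Character vector of bare chromosome names.
#' @export
normalize_chromosome <- function(chr) {
  out <- sub("^chr", "", as.character(chr))
  bad <- setdiff(unique(out), CHROMOSOMES)
  if (length(bad) > 0)
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  out
}

#' Read the probe annotation table
#'
#' Expected TSV columns: \code{probe_id}, \code{gene} (empty string allowed
#' for probes not linked to a gene), \code{chromosome} (with or without a
#' \code{"chr"} prefix), \code{position} (1-based), \code{in_cpg_island}
#' (logical) and \code{platform} (\code{meth27k}, \code{meth450k},
#' \code{expr_array} or \code{rnaseq}).
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per probe; chromosomes normalized to bare
#'   names.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = character(0))
  validate_probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param df A data.frame to validate in place of reading a file.
#' @export
validate_probe_annotation <- function(df) {
  need <- c("probe_id", "gene", "chromosome", "position", "in_cpg_island",
            "platform")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("probe annotation missing columns: ", paste(miss, collapse = ", "))
  df$chromosome <- normalize_chromosome(df$chromosome)
  df$in_cpg_island <- as.logical(df$in_cpg_island)
  bad_pf <- setdiff(unique(df$platform),
                    c("meth27k", "meth450k", "expr_array", "rnaseq"))
  if (length(bad_pf) > 0)
    stop("invalid platform values: ", paste(bad_pf, collapse = ", "))
  dup <- df$probe_id[ave(seq_len(nrow(df)), df$platform,
                         FUN = function(i) duplicated(df$probe_id[i]))
                     == 1]
  if (length(dup) > 0)
    stop("duplicate probe ids within a platform: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  if (any(is.na(df$position)) || any(df$position < 1))
    stop("position must be a positive 1-based integer")
  df
}

#' Write a JSON run report
#'
#' Every pipeline stage emits a JSON report of its parameters and headline
#' counts so a run can be audited.
#'
#' @param report A named list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
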