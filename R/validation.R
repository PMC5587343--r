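#' Knockdown differential-expression filter
#'
#' Selects genes whose expression changed after a knockdown, from
#' two-replicate knockdown and control FPKM tables. Values are first raised
#' to the expression floor (default 0.5 FPKM). A gene passes when (1) the
#' fold change between arm means exceeds 2, (2) both knockdown replicates
#' individually show a fold change above 1.5 against the controls, and (3)
#' both replicates agree in direction. All inequalities are strict.
#'
#' By default each replicate is compared with the mean of the two controls;
#' \code{replicate_mode = "each_vs_each"} instead requires all four pairwise
#' knockdown-vs-control folds to exceed the replicate cutoff.
#'
#' @param expr_kd Gene-by-replicate matrix (linear FPKM-like), knockdown arm.
#' @param expr_ctrl Matching control arm.
#' @param floor Linear expression floor, default 0.5.
#' @param mean_fold_cutoff Arm-mean fold cutoff, default 2.
#' @param replicate_fold_cutoff Per-replicate fold cutoff, default 1.5.
#' @param replicate_mode \code{"vs_ctrl_mean"} (default) or
#'   \code{"each_vs_each"}.
#' @return A data.frame with one row per gene: arm means, \code{mean_fold}
#'   (larger mean over smaller), per-replicate folds, \code{direction}
#'   (\code{up}/\code{down}, the knockdown relative to control) and
#'   \code{passes}.
#' @export
de_filter <- function(expr_kd, expr_ctrl, floor = 0.5,
                      mean_fold_cutoff = 2, replicate_fold_cutoff = 1.5,
                      replicate_mode = c("vs_ctrl_mean", "each_vs_each")) {
  replicate_mode <- match.arg(replicate_mode)
  expr_kd <- as.matrix(expr_kd); expr_ctrl <- as.matrix(expr_ctrl)
  stopifnot(nrow(expr_kd) == nrow(expr_ctrl))
  if (is.null(rownames(expr_kd)))
    rownames(expr_kd) <- rownames(expr_ctrl) <-
      sprintf("gene_%d", seq_len(nrow(expr_kd)))
  kd <- pmax(expr_kd, floor); ctrl <- pmax(expr_ctrl, floor)
  kd_mean <- rowMeans(kd); ctrl_mean <- rowMeans(ctrl)
  mean_fold <- pmax(kd_mean, ctrl_mean) / pmin(kd_mean, ctrl_mean)
  direction <- ifelse(kd_mean > ctrl_mean, "up", "down")
  # direction-consistent per-replicate folds: each knockdown replicate
  # against the control arm
  if (replicate_mode == "vs_ctrl_mean") {
    rep_fold <- ifelse(kd > ctrl_mean, kd / ctrl_mean, ctrl_mean / kd)
    rep_dir_up <- kd > ctrl_mean
    rep_pass <- rep_fold > replicate_fold_cutoff
  } else {
    folds <- lapply(seq_len(ncol(ctrl)), function(j) {
      f <- ifelse(kd > ctrl[, j], kd / ctrl[, j], ctrl[, j] / kd)
      f > replicate_fold_cutoff
    })
    rep_pass <- Reduce(`&`, folds)
    rep_fold <- ifelse(kd > ctrl_mean, kd / ctrl_mean, ctrl_mean / kd)
    rep_dir_up <- kd > ctrl_mean
  }
  dir_consistent <- rowSums(rep_dir_up) %in% c(0L, ncol(kd)) &
    (rowSums(rep_dir_up) == ncol(kd)) == (direction == "up")
  passes <- mean_fold > mean_fold_cutoff &
    rowSums(rep_pass) == ncol(kd) & dir_consistent
  data.frame(
    gene = rownames(kd),
    kd_mean = unname(kd_mean), ctrl_mean = unname(ctrl_mean),
    mean_fold = unname(mean_fold),
    rep_fold_1 = unname(rep_fold[, 1]), rep_fold_2 = unname(rep_fold[, 2]),
    direction = unname(direction), passes = unname(passes),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantify promoter methylation from McrBC-digestion qPCR
#'
#' McrBC cleaves methylated-CpG-containing DNA, so a qPCR amplicon spanning a
#' CpG island amplifies from the digested template only when it was
#' unmethylated. Methylation is quantified as the cycle-threshold difference
#' between the digested and the undigested (mock) reaction:
#' \code{delta_ct = ct_digested - ct_mock}. Each ~3.3 cycles of delay
#' corresponds to a 10-fold loss of intact template.
#'
#' @param records Data.frame with columns \code{sample_id},
#'   \code{ct_digested}, \code{ct_mock}. A reaction that failed to amplify
#'   is encoded as \code{NA}.
#' @param call_threshold_ct Delta-Ct at or above which a sample is called
#'   methylated, default 3 cycles (about 8-fold template loss).
#' @return The input with \code{delta_ct}, \code{methylated_call} and
#'   \code{evaluable} columns. A sample whose digested reaction failed while
#'   the mock amplified is called methylated (complete digestion); a failed
#'   mock reaction makes the sample unevaluable.
#' @export
mcrbc_quantify <- function(records, call_threshold_ct = 3) {
  need <- c("sample_id", "ct_digested", "ct_mock")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$ct_digested <= 0 | records$ct_mock <= 0, na.rm = TRUE))
    stop("Ct values must be positive")
  mock_ok <- !is.na(records$ct_mock)
  dig_ok <- !is.na(records$ct_digested)
  records$evaluable <- mock_ok
  records$delta_ct <- ifelse(mock_ok & dig_ok,
                             records$ct_digested - records$ct_mock,
                             NA_real_)
  records$methylated_call <- ifelse(
    !mock_ok, NA,
    ifelse(!dig_ok, TRUE, records$delta_ct >= call_threshold_ct))
  records
}
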