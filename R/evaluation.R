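# CASP-style QA assessment metrics: Diff, MCC at a GDT_TS threshold, AUC,
# Loss, per-target mean and pooled Pearson correlations, top-k overlap.

check_same_length <- function(predicted, true) {
  if (length(predicted) != length(true))
    stop("predicted and true score vectors differ in length (",
         length(predicted), " vs ", length(true), ")")
}

#' Mean absolute difference between predicted and true scores
#'
#' Both vectors must be on the same scale (GDT_TS units).
#'
#' @param predicted,true numeric vectors of equal length.
#' @return mean absolute difference.
#' @export
diff_metric <- function(predicted, true) {
  check_same_length(predicted, true)
  mean(abs(predicted - true))
}

#' Matthews correlation coefficient at a quality threshold
#'
#' Both vectors are binarized at the threshold (default 50 GDT_TS) and
#' the MCC of the two classifications is returned; any zero factor in the
#' denominator yields 0 by convention.
#'
#' @param predicted,true numeric vectors of equal length.
#' @param threshold binarization threshold.
#' @return MCC in \[-1, 1\].
#' @export
mcc_metric <- function(predicted, true, threshold = 50) {
  check_same_length(predicted, true)
  p <- predicted >= threshold
  t_ <- true >= threshold
  tp <- sum(p & t_); tn <- sum(!p & !t_)
  fp <- sum(p & !t_); fn <- sum(!p & t_)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Rank-based AUC of predicted score for true-class separation
#'
#' Mann-Whitney AUC of the predicted score for classifying models with
#' true quality >= threshold; tied scores contribute 1/2. With only one
#' true class the AUC is undefined and `NA` is returned with a warning.
#'
#' @inheritParams mcc_metric
#' @return AUC in \[0, 1\] or `NA`.
#' @export
auc_metric <- function(predicted, true, threshold = 50) {
  check_same_length(predicted, true)
  pos <- true >= threshold
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("only one true class present; AUC undefined")
    return(NA_real_)
  }
  r <- rank(predicted)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Loss: quality gap between the best model and the predicted best
#'
#' `max(true) - true[argmax(predicted)]`; ties in the predicted argmax
#' are broken lexicographically by model id (a neutral rule that never
#' peeks at the true scores).
#'
#' @inheritParams mcc_metric
#' @param model_ids optional ids used for tie-breaking; defaults to the
#'   element order.
#' @return loss in true-score units (>= 0).
#' @export
loss_metric <- function(predicted, true, model_ids = NULL) {
  check_same_length(predicted, true)
  if (is.null(model_ids)) model_ids <- sprintf("m%06d", seq_along(predicted))
  cand <- which(predicted == max(predicted))
  best <- cand[order(model_ids[cand])][1]
  max(true) - true[best]
}

#' Per-target mean and pooled Pearson correlations
#'
#' `mpcc` is the unweighted mean over targets of the per-target Pearson
#' correlation between predicted and true scores (zero-variance targets
#' excluded with a warning); `pcc` pools all models of all targets.
#'
#' @param predicted,true lists of numeric vectors, one element per target.
#' @return named numeric: `mpcc`, `pcc`.
#' @export
correlation_metrics <- function(predicted, true) {
  stopifnot(is.list(predicted), is.list(true),
            length(predicted) == length(true))
  per <- mapply(function(p, t_) {
    check_same_length(p, t_)
    if (length(p) < 2 || sd(p) < 1e-12 || sd(t_) < 1e-12) return(NA_real_)
    cor(p, t_)
  }, predicted, true)
  if (any(is.na(per)))
    warning(sum(is.na(per)), " target(s) with zero variance or < 2 models ",
            "excluded from mPCC")
  if (all(is.na(per))) return(c(mpcc = NA_real_, pcc = NA_real_))
  allp <- unlist(predicted); allt <- unlist(true)
  c(mpcc = mean(per, na.rm = TRUE), pcc = cor(allp, allt))
}

#' Overlap of the top-k models of two rankings
#'
#' @param ranking_a,ranking_b character vectors of model ids, best first,
#'   over the same id set of length >= k.
#' @param k depth of the comparison.
#' @return integer in \[0, k\].
#' @export
topk_overlap <- function(ranking_a, ranking_b, k = 5) {
  if (!setequal(ranking_a, ranking_b))
    stop("the two rankings cover different model sets")
  if (length(ranking_a) < k)
    stop("rankings shorter than k = ", k)
  length(intersect(head(ranking_a, k), head(ranking_b, k)))
}

#' Full evaluation report for one or more targets
#'
#' Computes Diff, MCC, AUC, Loss (per target, then averaged) plus the
#' per-target mean and pooled correlations, and a per-target breakdown
#' table.
#'
#' @param predicted,true lists of numeric vectors named by model id, one
#'   element per target (plain vectors are treated as a single target).
#' @param threshold MCC/AUC binarization threshold in GDT_TS units.
#' @return an `EvalReport`: list with `diff`, `mcc`, `auc`, `loss`,
#'   `mpcc`, `pcc`, `per_target` (data.frame).
#' @export
evaluate_predictions <- function(predicted, true, threshold = 50) {
  if (!is.list(predicted)) { predicted <- list(predicted); true <- list(true) }
  stopifnot(length(predicted) == length(true))
  tnames <- names(predicted)
  if (is.null(tnames)) tnames <- sprintf("target%02d", seq_along(predicted))
  rows <- mapply(function(p, t_, nm) {
    ids <- names(p)
    if (!is.null(ids) && !is.null(names(t_))) t_ <- t_[ids]
    data.frame(target = nm, n = length(p),
               diff = diff_metric(p, t_),
               loss = loss_metric(p, t_, model_ids = ids),
               pcc = if (length(p) >= 2 && sd(p) > 1e-12 && sd(t_) > 1e-12)
                 cor(p, t_) else NA_real_,
               stringsAsFactors = FALSE)
  }, predicted, true, tnames, SIMPLIFY = FALSE)
  per_target <- do.call(rbind, rows)
  allp <- unlist(predicted); allt <- unlist(true)
  cm <- suppressWarnings(correlation_metrics(predicted, true))
  structure(list(diff = mean(per_target$diff),
                 mcc = mcc_metric(allp, allt, threshold),
                 auc = suppressWarnings(auc_metric(allp, allt, threshold)),
                 loss = mean(per_target$loss),
                 mpcc = cm[["mpcc"]], pcc = cm[["pcc"]],
                 threshold = threshold, per_target = per_target),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("<EvalReport>  (threshold", x$threshold, "GDT_TS)\n")
  cat(sprintf("  Diff %.3f | MCC %.3f | AUC %s | Loss %.3f | mPCC %s | PCC %s\n",
              x$diff, x$mcc,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$loss,
              ifelse(is.na(x$mpcc), "NA", sprintf("%.3f", x$mpcc)),
              ifelse(is.na(x$pcc), "NA", sprintf("%.3f", x$pcc))))
  cat("  ", nrow(x$per_target), "target(s)\n")
  invisible(x)
}

#' Write an evaluation report as JSON and delimited text
#'
#' @param report an `EvalReport`.
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>_per_target.tsv`.
#' @return the two paths, invisibly.
#' @export
write_eval_report <- function(report, prefix) {
  jpath <- paste0(prefix, ".json")
  tpath <- paste0(prefix, "_per_target.tsv")
  jsonlite::write_json(unclass(report)[c("diff", "mcc", "auc", "loss",
                                         "mpcc", "pcc", "threshold")],
                       jpath, auto_unbox = TRUE, digits = NA, na = "null")
  write.table(report$per_target, tpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(jpath, tpath))
}
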