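# Quasi-clustering stage: the top-ranked models become references and
# every model is scored by its mean similarity to the references.

#' Select the reference models from a ranking
#'
#' Takes the first `k` (default 5) model ids of the ranking; a ranking
#' shorter than `k` yields all models with a warning.
#'
#' @param ranking a `RankingResult` from [rank_models()].
#' @param k number of references.
#' @return character vector of reference model ids, in ranked order.
#' @export
select_references <- function(ranking, k = 5) {
  if (!nrow(ranking)) stop("empty ranking")
  if (nrow(ranking) < k)
    warning("only ", nrow(ranking), " models available; using all as references")
  head(ranking$model_id, k)
}

#' Quasi-clustering quality scores
#'
#' Predicted quality of every model = its mean similarity (GDT_TS by
#' default, TM-score selectable) to the reference models. A reference
#' model is averaged over the other references only, so self-similarity
#' never inflates its score. Pairs whose similarity cannot be computed
#' are dropped from the mean with a warning; a model with no computable
#' similarity is flagged `NA`.
#'
#' @param decoy_set a [decoy_set()].
#' @param reference_ids model ids from [select_references()].
#' @param metric `"GDT_TS"` (default) or `"TM-score"`.
#' @return a `QuasiResult`: list with `reference_ids`, `scores` (named by
#'   model id, on the metric scale) and `metric`.
#' @export
quasi_scores <- function(decoy_set, reference_ids, metric = "GDT_TS") {
  ids <- names(decoy_set$models)
  missing_refs <- setdiff(reference_ids, ids)
  if (length(missing_refs))
    stop("reference model(s) not in the decoy set: ",
         paste(missing_refs, collapse = ", "))
  fun <- metric_fun(metric)
  # model x reference similarity block, computed once
  sim <- matrix(NA_real_, length(ids), length(reference_ids),
                dimnames = list(ids, reference_ids))
  n_failed <- 0L
  for (r in reference_ids) {
    ref <- decoy_set$models[[r]]
    for (m in ids) {
      if (m == r) { sim[m, r] <- metric_self_value(metric); next }
      v <- tryCatch(fun(decoy_set$models[[m]], ref)$value,
                    error = function(e) NA_real_)
      if (is.na(v)) n_failed <- n_failed + 1L
      sim[m, r] <- v
    }
  }
  if (n_failed > 0L)
    warning(n_failed, " model-reference pair(s) not comparable; ",
            "dropped from the averages")
  scores <- vapply(ids, function(m) {
    use <- setdiff(reference_ids, m)  # self-exclusion for references
    mean(sim[m, use], na.rm = TRUE)
  }, numeric(1))
  scores[is.nan(scores)] <- NA_real_
  structure(list(reference_ids = reference_ids,
                 scores = setNames(scores, ids), metric = metric),
            class = "QuasiResult")
}

#' @export
print.QuasiResult <- function(x, ...) {
  cat("<QuasiResult>", x$metric, "- references:",
      paste(x$reference_ids, collapse = ", "), "\n")
  print(round(x$scores, 2))
  invisible(x)
}
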