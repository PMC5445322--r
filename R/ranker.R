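# Pairwise via-classification learning-to-rank: decoy pairs of one target
# become labeled feature-difference instances, a linear large-margin
# classifier is fitted on them (L2-regularized hinge loss via libsvm),
# and its weight vector scores new decoys; higher score = better model.

#' Build labeled pair instances from a feature table
#'
#' For every unordered pair of models of the same target whose true
#' qualities differ by more than `margin`, emits one difference instance
#' in canonical orientation (higher-quality model first, label +1); with
#' `symmetrize = TRUE` every second instance is sign-flipped for class
#' balance. Pairs are never formed across targets.
#'
#' @param tables a `FeatureTable` or list of them (same columns).
#' @param true_quality numeric vector named by model id (GDT_TS to the
#'   native, or TM-score), or a list parallel to `tables`.
#' @param margin tie margin in quality units; pairs with
#'   `|delta| <= margin` are dropped.
#' @param max_pairs per-target cap; excess pairs are subsampled
#'   deterministically under `seed`.
#' @param symmetrize flip the sign of alternating instances.
#' @param seed RNG seed for subsampling.
#' @return a `PairSet`: list with `diffs` (instance x feature matrix),
#'   `labels` (+1/-1), `targets`, and pooled normalization `center` /
#'   `scale`.
#' @export
make_pairs <- function(tables, true_quality, margin = 0, max_pairs = 50000,
                       symmetrize = TRUE, seed = 1) {
  if (inherits(tables, "FeatureTable")) {
    tables <- list(tables)
    true_quality <- list(true_quality)
  }
  stopifnot(length(tables) == length(true_quality))
  cols <- colnames(tables[[1]]$features)
  all_rows <- do.call(rbind, lapply(tables, function(t) t$features))
  center <- colMeans(all_rows)
  scale <- apply(all_rows, 2, sd)
  scale[scale < 1e-12] <- 1
  diffs <- list(); labels <- list(); targets <- list()
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    if (!identical(colnames(tb$features), cols))
      stop("feature tables have differing columns")
    q <- true_quality[[k]][tb$model_ids]
    if (any(is.na(q)))
      stop("missing true quality for model(s) of target ", tb$target_id)
    n <- length(q)
    if (n < 2) next
    pr <- t(combn(n, 2))
    dq <- q[pr[, 1]] - q[pr[, 2]]
    keep <- abs(dq) > margin
    pr <- pr[keep, , drop = FALSE]; dq <- dq[keep]
    if (nrow(pr) == 0L) next
    # canonical orientation: higher-quality model first
    flip <- dq < 0
    hi <- ifelse(flip, pr[, 2], pr[, 1])
    lo <- ifelse(flip, pr[, 1], pr[, 2])
    if (nrow(pr) > max_pairs) {
      set.seed(seed + k)
      sel <- sort(sample.int(nrow(pr), max_pairs))
      hi <- hi[sel]; lo <- lo[sel]
    }
    d <- tb$features[hi, , drop = FALSE] - tb$features[lo, , drop = FALSE]
    lab <- rep(1, nrow(d))
    if (symmetrize) {
      sw <- seq_len(nrow(d)) %% 2 == 0
      d[sw, ] <- -d[sw, , drop = FALSE]
      lab[sw] <- -1
    }
    diffs[[length(diffs) + 1L]] <- d
    labels[[length(labels) + 1L]] <- lab
    targets[[length(targets) + 1L]] <- rep(tb$target_id, nrow(d))
  }
  if (length(diffs) == 0L) {
    warning("all model pairs are tied; empty pair set")
    return(structure(list(diffs = matrix(numeric(0), 0, length(cols),
                                         dimnames = list(NULL, cols)),
                          labels = numeric(0), targets = character(0),
                          center = center, scale = scale),
                     class = "PairSet"))
  }
  structure(list(diffs = do.call(rbind, diffs),
                 labels = unlist(labels),
                 targets = unlist(targets),
                 center = center, scale = scale),
            class = "PairSet")
}

#' Fit the linear ranking model
#'
#' Trains a linear large-margin classifier (C-classification, i.e.
#' L2-regularized hinge loss) on the normalized difference instances; the
#' learned hyperplane normal is the ranking weight vector. The bias is
#' fixed at 0: a ranking score is translation-free.
#'
#' @param pairs a `PairSet` from [make_pairs()].
#' @param C soft-margin regularization constant.
#' @param seed stored in the model metadata; the fit itself is
#'   deterministic given the pair set.
#' @return a `RankModel`: list with `weights` (per feature, normalized
#'   space), `bias = 0`, `center`, `scale`, `C` and `meta` (seed, pair
#'   count, training pair accuracy).
#' @export
fit_rank_model <- function(pairs, C = 1, seed = 1) {
  if (!inherits(pairs, "PairSet")) stop("not a PairSet")
  if (nrow(pairs$diffs) < 1) stop("empty pair set")
  X <- sweep(pairs$diffs, 2, pairs$scale, "/")
  y <- pairs$labels
  if (length(unique(y)) == 1L) {
    # single-orientation input: symmetrize by mirroring
    X <- rbind(X, -X)
    y <- c(y, -y)
  }
  set.seed(seed)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  acc <- mean(sign(X %*% w) == y)
  if (acc < 0.5) { w <- -w; acc <- 1 - acc }
  names(w) <- colnames(pairs$diffs)
  structure(list(weights = w, bias = 0,
                 center = pairs$center, scale = pairs$scale, C = C,
                 meta = list(seed = seed, n_pairs = nrow(pairs$diffs),
                             train_pair_accuracy = acc)),
            class = "RankModel")
}

#' @export
print.RankModel <- function(x, ...) {
  cat("<RankModel>", length(x$weights), "features, C =", x$C,
      sprintf("(train pair accuracy %.3f)\n", x$meta$train_pair_accuracy))
  print(round(x$weights, 4))
  invisible(x)
}

#' Score and order the models of a feature table
#'
#' Rank score = `weights . (x - center) / scale`; models are ordered by
#' non-increasing score with ties broken lexicographically by model id.
#'
#' @param model a `RankModel`.
#' @param table a `FeatureTable` whose columns match the model's.
#' @return a `RankingResult`: data.frame with `model_id` and `score`,
#'   best first.
#' @export
rank_models <- function(model, table) {
  cols <- names(model$weights)
  have <- colnames(table$features)
  if (!identical(sort(cols), sort(have))) {
    stop("feature columns do not match the model; missing: ",
         paste(setdiff(cols, have), collapse = ", "), "; extra: ",
         paste(setdiff(have, cols), collapse = ", "))
  }
  X <- sweep(sweep(table$features[, cols, drop = FALSE], 2, model$center),
             2, model$scale, "/")
  score <- drop(X %*% model$weights) + model$bias
  ord <- order(-score, table$model_ids)
  res <- data.frame(model_id = table$model_ids[ord], score = score[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("RankingResult", "data.frame")
  res
}

#' Target-level cross-validation of the ranker
#'
#' Splits targets (never models) into folds, fits on the training folds
#' and reports per-target statistics of the held-out rank scores against
#' the true qualities.
#'
#' @param tables list of `FeatureTable`s, one per target.
#' @param true_quality list of named quality vectors, parallel to `tables`.
#' @param folds number of folds (must not exceed the target count).
#' @param margin,C,seed passed to [make_pairs()] / [fit_rank_model()];
#'   `seed` also fixes the fold assignment.
#' @return data.frame with one row per target: `target`, `fold`, `pcc`,
#'   `kendall`, `loss`.
#' @export
cross_validate <- function(tables, true_quality, folds = 5, margin = 0,
                           C = 1, seed = 1) {
  nt <- length(tables)
  if (folds > nt) stop("more folds (", folds, ") than targets (", nt, ")")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), nt))
  out <- list()
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    ps <- make_pairs(tables[tr], true_quality[tr], margin = margin,
                     seed = seed)
    rm_ <- fit_rank_model(ps, C = C, seed = seed)
    for (k in te) {
      rk <- rank_models(rm_, tables[[k]])
      q <- true_quality[[k]][rk$model_id]
      out[[length(out) + 1L]] <- data.frame(
        target = tables[[k]]$target_id, fold = f,
        pcc = suppressWarnings(cor(rk$score, q)),
        kendall = suppressWarnings(cor(rk$score, q, method = "kendall")),
        loss = max(q) - q[1],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Save / load a RankModel as JSON
#'
#' @param model a `RankModel`.
#' @param path JSON file path.
#' @return `path` (write) or the `RankModel` (read).
#' @export
write_rank_model <- function(model, path) {
  obj <- unclass(model)
  # named vectors must serialize as JSON objects, not bare arrays
  obj$weights <- as.list(obj$weights)
  obj$center <- as.list(obj$center)
  obj$scale <- as.list(obj$scale)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rank_model
#' @export
read_rank_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  obj$weights <- unlist(obj$weights)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  structure(obj, class = "RankModel")
}
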