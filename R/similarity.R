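# Structure similarity between models of the same sequence: Kabsch
# superposition, GDT_TS and TM-score.  Alignment is always by residue
# index (decoys share the target sequence); no structural alignment.

GDT_THRESHOLDS <- c(1, 2, 4, 8)

# Seed-window lengths for the iterative search.  Short chains get every
# contiguous window length; long chains a fixed ladder plus n/4, n/2, n.
gdt_window_lengths <- function(n) {
  if (n <= 32) 3:n else unique(c(3:7, floor(n / 4), floor(n / 2), n))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `coords_a` onto `coords_b` with
#' reflections excluded. The fitted coordinates are
#' `coords_a %*% rotation + translation` (row vectors).
#'
#' @param coords_a,coords_b matched N x 3 coordinate matrices (N >= 3).
#' @return a `Superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) < 3) stop("at least 3 paired points are required")
  sv <- svd(scale(coords_a, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv))
    warning("(near-)collinear point set; superposition is ill-determined")
  fit <- cpp_kabsch(coords_a, coords_b)
  structure(list(rotation = fit$rotation,
                 translation = as.numeric(fit$translation),
                 rmsd = fit$rmsd),
            class = "Superposition")
}

# matched CA coordinate pair (model vs reference) on shared residue indices
matched_ca <- function(model, reference) {
  pm <- ca_xyz(model)
  pr <- ca_xyz(reference)
  common <- intersect(rownames(pm), rownames(pr))
  list(model = pm[common, , drop = FALSE],
       ref = pr[common, , drop = FALSE],
       n_common = length(common),
       n_ref = nrow(pr))
}

similarity_score <- function(metric, value, per_threshold = NULL) {
  structure(list(metric = metric, value = value,
                 per_threshold = per_threshold),
            class = "SimilarityScore")
}

#' @export
print.SimilarityScore <- function(x, ...) {
  cat("<SimilarityScore>", x$metric, "=", format(x$value, digits = 6), "\n")
  if (!is.null(x$per_threshold))
    cat("  P1/P2/P4/P8:", paste(format(x$per_threshold, digits = 5),
                                collapse = " "), "\n")
  invisible(x)
}

#' GDT_TS structure similarity
#'
#' Global Distance Test Total Score of a model against a reference of the
#' same sequence: the mean over distance thresholds 1, 2, 4 and 8 Angstrom
#' of the maximal percentage of CA pairs superposable within the
#' threshold. The maximum is searched by LGA-style iterative seeding:
#' every seed window is superposed, inliers under the threshold are
#' refitted until a fixed point (at most `max_iter` rounds), and the best
#' inlier count is kept. The denominator is the number of reference
#' residues, so residues missing from the model count as unfit.
#'
#' @param model,reference [structure_model()] objects sharing >= 3 residue
#'   indices with CA atoms.
#' @param max_iter iteration cap per seed.
#' @return a `SimilarityScore` with `value` in \[0, 100\] and
#'   `per_threshold` percentages P1, P2, P4, P8.
#' @export
gdt_ts <- function(model, reference, max_iter = 10) {
  m <- matched_ca(model, reference)
  if (m$n_common < 3)
    stop("models share fewer than 3 residues with CA atoms")
  counts <- cpp_gdt_counts(m$model, m$ref, GDT_THRESHOLDS,
                           gdt_window_lengths(m$n_common), max_iter)
  pt <- 100 * counts / m$n_ref
  names(pt) <- paste0("P", GDT_THRESHOLDS)
  similarity_score("GDT_TS", mean(pt), pt)
}

# TM-score normalization length -> d0 (standard published form)
tm_d0 <- function(L) {
  if (L < 16) {
    warning("reference shorter than 16 residues; using fixed d0 = 0.5 A")
    return(0.5)
  }
  max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
}

# TM sum for a vector of paired distances (internal; exercised in tests)
tm_from_dist <- function(d, d0) sum(1 / (1 + (d / d0)^2))

#' TM-score structure similarity
#'
#' Template Modeling score of a model against a reference of the same
#' sequence, normalized by the reference length L with
#' d0 = 1.24 (L - 15)^(1/3) - 1.8 Angstrom (fixed d0 = 0.5 for L < 16).
#' Uses the same iterative fragment search as [gdt_ts()], keeping the
#' superposition that maximizes the TM sum.
#'
#' @inheritParams gdt_ts
#' @return a `SimilarityScore` with `value` in (0, 1\].
#' @export
tm_score <- function(model, reference, max_iter = 10) {
  m <- matched_ca(model, reference)
  if (m$n_common < 3)
    stop("models share fewer than 3 residues with CA atoms")
  d0 <- tm_d0(m$n_ref)
  best <- cpp_tm_best(m$model, m$ref, d0,
                      gdt_window_lengths(m$n_common), max_iter)
  similarity_score("TM-score", best / m$n_ref)
}

metric_fun <- function(metric) {
  metric <- normalize_metric(metric)
  if (metric == "GDT_TS") gdt_ts else tm_score
}

normalize_metric <- function(metric) {
  m <- toupper(gsub("[-_ ]", "", metric))
  if (m %in% c("GDTTS", "GDT")) return("GDT_TS")
  if (m %in% c("TMSCORE", "TM")) return("TM-score")
  stop("unknown similarity metric: ", metric)
}

metric_self_value <- function(metric) {
  if (normalize_metric(metric) == "GDT_TS") 100 else 1
}

#' All-against-all similarity matrix
#'
#' Entry (i, j) scores model i against reference model j. The diagonal is
#' the metric's self-similarity (100 for GDT_TS, 1 for TM-score). Pairs
#' sharing fewer than 3 CA residues are flagged `NA` (missing), never 0.
#'
#' @param models list of [structure_model()] objects (>= 2).
#' @param metric `"GDT_TS"` (default) or `"TM-score"`.
#' @return numeric matrix with model ids as dimnames.
#' @export
pairwise_similarity_matrix <- function(models, metric = "GDT_TS") {
  if (length(models) < 2) stop("need at least 2 models")
  ids <- vapply(models, function(m) m$model_id, character(1))
  fun <- metric_fun(metric)
  n <- length(models)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(out) <- metric_self_value(metric)
  n_missing <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- tryCatch(fun(models[[i]], models[[j]])$value, error = function(e) NA_real_)
    if (is.na(v)) n_missing <- n_missing + 1L
    out[i, j] <- v
  }
  if (n_missing > 0L)
    warning(n_missing, " model pair(s) share too few residues; ",
            "entries flagged missing")
  out
}

#' Export a similarity matrix as delimited text
#'
#' @param mat matrix from [pairwise_similarity_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(mat, path, sep = "\t") {
  write.table(cbind(model_id = rownames(mat), as.data.frame(mat)),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
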