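# Per-model feature assembly: three-state secondary-structure assignment
# from backbone geometry, Shrake-Rupley solvent accessibility, agreement
# features against sequence-based predictions, external score tables, and
# the combined feature table the ranker consumes.

#' Assign three-state secondary structure from backbone geometry
#'
#' Dihedral-based assignment: residues whose (phi, psi) fall in the
#' helical region are labeled H, extended-region residues E, everything
#' else (including residues with missing backbone atoms and chain
#' termini) C. Runs shorter than 4 (H) or 3 (E) are smoothed to coil, as
#' geometry-based assigners do.
#'
#' @param model a [structure_model()] object.
#' @return an `SSProfile`: list with `labels` (character vector named by
#'   residue index, alphabet H/E/C) and `source = "assigned-from-model"`.
#' @export
assign_secondary_structure <- function(model) {
  tor <- backbone_dihedrals(model)
  n <- nrow(tor)
  lab <- rep("C", n)
  if (n >= 3) {
    phi <- tor$phi; psi <- tor$psi
    helix <- !is.na(phi) & !is.na(psi) &
      phi > -120 & phi < -20 & psi > -80 & psi < 30
    strand <- !is.na(phi) & !is.na(psi) &
      phi > -180 & phi < -60 & (psi > 60 | psi < -150)
    lab[strand] <- "E"
    lab[helix] <- "H"
    lab <- smooth_ss_runs(lab, min_h = 4, min_e = 3)
  } else {
    warning("fewer than 3 residues with backbone; all-coil profile")
  }
  structure(list(labels = setNames(lab, tor$resno),
                 source = "assigned-from-model"),
            class = "SSProfile")
}

smooth_ss_runs <- function(lab, min_h = 4, min_e = 3) {
  r <- rle(lab)
  short <- (r$values == "H" & r$lengths < min_h) |
    (r$values == "E" & r$lengths < min_e)
  r$values[short] <- "C"
  inverse.rle(r)
}

#' Secondary-structure consistency features
#'
#' Per-element agreement between an assigned and a predicted three-state
#' profile: for each of H, E and C the fraction of positions where both
#' profiles carry that label, plus the total fraction of agreeing
#' positions (which equals the sum of the three).
#'
#' @param assigned,predicted `SSProfile` objects or plain character
#'   vectors over H/E/C of equal length.
#' @return named numeric: `ss_H`, `ss_E`, `ss_C`, `ss_total`, all in
#'   \[0, 1\].
#' @export
ss_consistency_features <- function(assigned, predicted) {
  a <- if (inherits(assigned, "SSProfile")) assigned$labels else assigned
  p <- if (inherits(predicted, "SSProfile")) predicted$labels else predicted
  a <- unlist(strsplit(paste(a, collapse = ""), ""))
  p <- unlist(strsplit(paste(p, collapse = ""), ""))
  if (length(a) != length(p))
    stop("profile lengths differ: ", length(a), " vs ", length(p))
  L <- length(a)
  out <- vapply(c(H = "H", E = "E", C = "C"),
                function(e) sum(a == e & p == e) / L, numeric(1))
  c(ss_H = out[["H"]], ss_E = out[["E"]], ss_C = out[["C"]],
    ss_total = sum(a == p) / L)
}

# Deterministic, roughly uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per residue (Shrake-Rupley)
#'
#' Deterministic sphere-sampling SASA over the heavy atoms: each atom's
#' expanded sphere (van der Waals radius + probe) carries a fixed
#' golden-spiral point set; a point is accessible when outside every
#' neighboring expanded sphere. Per-residue values are sums over the
#' residue's atoms, in Angstrom^2.
#'
#' @param model a [structure_model()] object.
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points sphere sample points per atom.
#' @return an `SAProfile`: list with `values` (named by residue index),
#'   `kind = "absolute"`.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 120) {
  at <- heavy_atoms(model)
  resnos <- sort(unique(at$resno))
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- vdw_radius(at$elesy) + probe
  pts <- sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    dd <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(dd < rad[i] + rad & dd > 0)
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(sp, 2, xyz[j, ])^2)
      acc <- acc & d2 > rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  values <- vapply(resnos, function(r) sum(area[at$resno == r]), numeric(1))
  empty <- vapply(resnos, function(r) sum(at$resno == r) == 0L, logical(1))
  if (any(empty)) warning(sum(empty), " residue(s) with no atoms; SASA 0")
  structure(list(values = setNames(values, resnos), kind = "absolute"),
            class = "SAProfile")
}

#' Convert absolute SASA to relative accessibility
#'
#' Divides each residue's absolute SASA by the residue type's theoretical
#' maximum accessible area; unknown residues use the table mean. Values
#' are clamped to \[0, 1.5\].
#'
#' @param sa an `SAProfile` with `kind = "absolute"` (or a named numeric).
#' @param aa one-letter residue codes aligned with `sa`.
#' @return an `SAProfile` with `kind = "relative"`.
#' @export
relative_sasa <- function(sa, aa) {
  v <- if (inherits(sa, "SAProfile")) sa$values else sa
  if (length(v) != length(aa)) stop("SASA and residue vectors differ in length")
  mx <- MAX_ASA[toupper(aa)]
  mx[is.na(mx)] <- mean(MAX_ASA)
  rel <- pmin(pmax(v / mx, 0), 1.5)
  structure(list(values = setNames(rel, names(v)), kind = "relative"),
            class = "SAProfile")
}

#' Solvent-accessibility agreement features
#'
#' Compares the model-derived relative accessibility profile with a
#' predicted profile and returns the Pearson correlation and the cosine
#' of the two vectors. Zero-variance (correlation) or zero-norm (cosine)
#' profiles yield 0 with a warning.
#'
#' @param model_sa,predicted_sa `SAProfile` objects or numeric vectors of
#'   equal length >= 2 (relative scale).
#' @return named numeric: `sa_pcc`, `sa_cos`.
#' @export
sa_agreement_features <- function(model_sa, predicted_sa) {
  x <- if (inherits(model_sa, "SAProfile")) model_sa$values else model_sa
  y <- if (inherits(predicted_sa, "SAProfile")) predicted_sa$values else predicted_sa
  if (length(x) != length(y)) stop("profile lengths differ")
  if (length(x) < 2) stop("need at least 2 residues")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    warning("zero-variance accessibility profile; correlation set to 0")
    pcc <- 0
  } else pcc <- cor(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx < 1e-12 || ny < 1e-12) {
    warning("zero-norm accessibility profile; cosine set to 0")
    cosv <- 0
  } else cosv <- sum(x * y) / (nx * ny)
  c(sa_pcc = pcc, sa_cos = cosv)
}

#' Read a predicted secondary-structure file
#'
#' Accepts either a plain file whose concatenated non-comment lines form
#' an H/E/C string, or the PSIPRED "horiz" dialect (labels on `Pred:`
#' lines). 8-state letters are collapsed by the standard convention
#' (H/G/I to H, E/B to E, else C).
#'
#' @param path text file.
#' @return an `SSProfile` with `source = "predicted-from-sequence"`.
#' @export
read_ss_prediction <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^Pred:", lines))) {
    s <- paste(gsub("^Pred:\\s*", "", grep("^Pred:", lines, value = TRUE)),
               collapse = "")
  } else {
    s <- paste(trimws(lines[!startsWith(trimws(lines), "#")]), collapse = "")
  }
  s <- gsub("\\s", "", s)
  if (!nzchar(s)) stop("no secondary-structure string in '", path, "'")
  lab <- toupper(unlist(strsplit(s, "")))
  lab[lab %in% c("H", "G", "I")] <- "H"
  lab[lab %in% c("E", "B")] <- "E"
  lab[!(lab %in% c("H", "E"))] <- "C"
  structure(list(labels = setNames(lab, seq_along(lab)),
                 source = "predicted-from-sequence"),
            class = "SSProfile")
}

#' Read a predicted relative-accessibility file
#'
#' Whitespace-delimited per-residue relative accessibility fractions (one
#' or more values per line; `#` comments allowed).
#'
#' @param path text file.
#' @return an `SAProfile` with `kind = "relative"`.
#' @export
read_sa_prediction <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  v <- suppressWarnings(as.numeric(unlist(strsplit(paste(lines, collapse = " "),
                                                   "\\s+"))))
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no accessibility values in '", path, "'")
  structure(list(values = setNames(pmin(pmax(v, 0), 1.5), seq_along(v)),
                 kind = "relative"),
            class = "SAProfile")
}

#' Ingest an external per-model score table
#'
#' Reads a delimited text table (comma, tab or whitespace separated) with
#' a `model_id` column and one or more numeric score columns. Models of
#' the decoy set absent from the table are imputed at the per-column
#' median of the matched models.
#'
#' @param table_file delimited text file.
#' @param decoy_set a [decoy_set()].
#' @return numeric matrix (rows = decoy-set models, in set order) with an
#'   `n_imputed` attribute.
#' @export
ingest_external_scores <- function(table_file, decoy_set) {
  if (!file.exists(table_file)) stop("score table not found: ", table_file)
  first <- readLines(table_file, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tab <- read.table(table_file, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!("model_id" %in% names(tab)))
    stop("score table '", table_file, "' has no model_id column")
  if (anyDuplicated(tab$model_id))
    stop("duplicate model_id in '", table_file, "': ",
         paste(unique(tab$model_id[duplicated(tab$model_id)]), collapse = ", "))
  ids <- names(decoy_set$models)
  if (!any(ids %in% tab$model_id))
    stop("no overlapping model ids between '", table_file,
         "' and the decoy set")
  score_cols <- setdiff(names(tab), "model_id")
  m <- as.matrix(tab[match(ids, tab$model_id), score_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  n_imputed <- sum(is.na(m[, 1]))
  for (cc in seq_len(ncol(m))) {
    med <- median(m[, cc], na.rm = TRUE)
    m[is.na(m[, cc]), cc] <- med
  }
  attr(m, "n_imputed") <- n_imputed
  m
}

#' Build the per-model feature table of a decoy set
#'
#' Assembles, in deterministic column order: the pair- and
#' torsion-potential energies, the four secondary-structure consistency
#' features and the two accessibility agreement features (when sequence
#' predictions are supplied), then any external score columns in file
#' order. Per-column mean/sd of the table are stored as the `norm`
#' attribute.
#'
#' @param decoy_set a [decoy_set()].
#' @param pair_potential optional `PairPotential`.
#' @param torsion_potential optional `TorsionPotential`.
#' @param predicted_ss optional `SSProfile` (target-length prediction).
#' @param predicted_sa optional `SAProfile` (target-length, relative).
#' @param external_files character vector of score-table files.
#' @return a `FeatureTable`: list with `target_id`, `model_ids`,
#'   `features` (model x feature matrix) and `provenance`.
#' @export
build_feature_table <- function(decoy_set, pair_potential = NULL,
                                torsion_potential = NULL,
                                predicted_ss = NULL, predicted_sa = NULL,
                                external_files = character()) {
  ids <- names(decoy_set$models)
  cols <- list()
  prov <- character()
  if (!is.null(pair_potential)) {
    cols$pair_energy <- vapply(decoy_set$models, function(m)
      score_pair_potential(m, pair_potential)$value, numeric(1))
    prov["pair_energy"] <- "native"
  }
  if (!is.null(torsion_potential)) {
    cols$torsion_energy <- vapply(decoy_set$models, function(m)
      score_torsion_potential(m, torsion_potential)$value, numeric(1))
    prov["torsion_energy"] <- "native"
  }
  if (!is.null(predicted_ss)) {
    ssm <- t(vapply(decoy_set$models, function(m) {
      assigned <- assign_secondary_structure(m)
      idx <- names(assigned$labels)
      pred <- predicted_ss$labels[idx]
      pred[is.na(pred)] <- "C"
      ss_consistency_features(assigned$labels, pred)
    }, c(ss_H = 0, ss_E = 0, ss_C = 0, ss_total = 0)))
    for (nm in colnames(ssm)) { cols[[nm]] <- ssm[, nm]; prov[nm] <- "native" }
  }
  if (!is.null(predicted_sa)) {
    sam <- t(vapply(decoy_set$models, function(m) {
      abs_sa <- compute_sasa(m)
      rel <- relative_sasa(abs_sa, residue_aa(m)[names(abs_sa$values)])
      idx <- names(rel$values)
      pred <- predicted_sa$values[idx]
      pred[is.na(pred)] <- 0
      suppressWarnings(sa_agreement_features(rel$values, pred))
    }, c(sa_pcc = 0, sa_cos = 0)))
    for (nm in colnames(sam)) { cols[[nm]] <- sam[, nm]; prov[nm] <- "native" }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(ids), ncol = 0)
  rownames(mat) <- ids
  for (f in external_files) {
    em <- ingest_external_scores(f, decoy_set)
    colnames(em) <- make.unique(c(colnames(mat), colnames(em)),
                                sep = "_")[ncol(mat) + seq_len(ncol(em))]
    prov[colnames(em)] <- paste0("external:", basename(f))
    mat <- cbind(mat, em)
  }
  if (ncol(mat) == 0L) stop("no features requested")
  if (any(!is.finite(mat))) stop("non-finite feature values")
  ft <- structure(list(target_id = decoy_set$target_id, model_ids = ids,
                       features = mat, provenance = prov),
                  class = "FeatureTable")
  attr(ft, "norm") <- list(center = colMeans(mat),
                           scale = apply(mat, 2, sd))
  ft
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat("<FeatureTable>", x$target_id, "-", nrow(x$features), "models x",
      ncol(x$features), "features\n")
  cat("  columns:", paste(colnames(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Export a feature table as delimited text
#'
#' @param table a `FeatureTable`.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = "\t") {
  df <- cbind(model_id = table$model_ids, as.data.frame(table$features))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
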