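# Reading, validating and writing decoy/native coordinate files.
#
# A StructureModel keeps the atoms of one model in a flat table (one row
# per atom: resno, aa, elety, elesy, x, y, z, is_h), the idiomatic R form
# for coordinate data; residue-level views are derived on demand.

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `resno` (1-based residue index),
#'   `aa` (one-letter code, 20 canonical + X), `elety` (atom name),
#'   `elesy` (element symbol), `x`, `y`, `z` (Angstrom) and `is_h`
#'   (hydrogen flag).
#' @param model_id identifier string.
#' @param source_path origin of the coordinates (file path or synthetic tag).
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, model_id, source_path = NA_character_) {
  required <- c("resno", "aa", "elety", "elesy", "x", "y", "z", "is_h")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("a StructureModel needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in model '", model_id, "'")
  if (any(atoms$elesy == "" | is.na(atoms$elesy)))
    stop("empty element symbol in model '", model_id, "'")
  if (any(atoms$resno < 1L))
    stop("residue indices must be >= 1 in model '", model_id, "'")
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  ca <- atoms[atoms$elety == "CA" & !atoms$is_h, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("model '", model_id, "' has no CA atoms")
  if (anyDuplicated(ca$resno))
    stop("duplicate CA atoms within a residue in model '", model_id, "'")
  structure(list(model_id = as.character(model_id), atoms = atoms,
                 source_path = as.character(source_path)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("<StructureModel>", x$model_id, "-", length(unique(x$atoms$resno)),
      "residues,", nrow(x$atoms), "atoms",
      sprintf("(%d hydrogens)\n", sum(x$atoms$is_h)))
  invisible(x)
}

# one-letter residue codes named by residue index
residue_aa <- function(model) {
  at <- model$atoms
  first <- !duplicated(at$resno)
  setNames(at$aa[first], at$resno[first])
}

# sequence residue indices present in the model
residue_indices <- function(model) sort(unique(model$atoms$resno))

# CA coordinates as an N x 3 matrix with residue indices as rownames
ca_xyz <- function(model) {
  ca <- model$atoms[model$atoms$elety == "CA" & !model$atoms$is_h, , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

# heavy-atom table (drops hydrogens)
heavy_atoms <- function(model) {
  model$atoms[!model$atoms$is_h, , drop = FALSE]
}

infer_element <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", toupper(elety))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("SE", "FE", "ZN", "MG", "CL", "BR"), two,
                substr(nm, 1, 1))
  # names like 1HB / HB2 are hydrogens
  out[grepl("^[0-9]*H", toupper(elety))] <- "H"
  out[out == ""] <- "C"
  out
}

#' Read one decoy or native model from a PDB file
#'
#' Parses the first coordinate model via bio3d, resolves alternate
#' locations (highest occupancy, then alphabetical altloc id), selects one
#' chain (by default the chain with the most CA atoms), maps common
#' nonstandard residues (e.g. MSE) to their parent amino acid, and flags
#' hydrogens.
#'
#' @param path PDB file path.
#' @param chain chain identifier to keep; default `NULL` picks the chain
#'   with the most CA atoms.
#' @param model_id identifier; default is the file name without extension.
#' @return a [structure_model()] object.
#' @export
read_pdb <- function(path, chain = NULL, model_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(model_id))
    model_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & toupper(at$resid) %in% names(AA_NONSTANDARD))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in '", path, "'")
  # altloc resolution: highest occupancy then alphabetical altloc
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$.orig <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$.orig), , drop = FALSE]  # restore file order
  # chain selection: requested chain, else most CA atoms
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) {
    ca_per_chain <- table(at$chain[at$elety == "CA"])
    if (length(ca_per_chain) == 0L)
      stop("model '", path, "' has no CA atoms")
    chain <- names(ca_per_chain)[which.max(ca_per_chain)]
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in '", path, "'")
  # drop insertion-code duplicates of a residue number (first kept)
  at <- at[order(at$resno, at$.orig), , drop = FALSE]
  elesy <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                          infer_element(at$elety), at$elesy))
  atoms <- data.frame(resno = as.integer(at$resno),
                      aa = aa3to1(at$resid),
                      elety = toupper(at$elety),
                      elesy = elesy,
                      x = at$x, y = at$y, z = at$z,
                      is_h = elesy %in% c("H", "D"),
                      stringsAsFactors = FALSE)
  dup <- duplicated(paste(atoms$resno, atoms$elety))
  atoms <- atoms[!dup, , drop = FALSE]
  structure_model(atoms, model_id = model_id, source_path = path)
}

#' Write a StructureModel as a PDB file
#'
#' Emits standard fixed-column ATOM records (single chain "A");
#' `read_pdb(write_pdb(m))` preserves residue count, atom names and
#' coordinates to the format precision of 1e-3 Angstrom.
#'
#' @param model a [structure_model()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  if (!inherits(model, "StructureModel")) stop("not a StructureModel")
  at <- model$atoms
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno,
                     resid = aa1to3(at$aa),
                     elety = at$elety,
                     chain = rep("A", nrow(at)),
                     o = rep(1, nrow(at)), b = rep(0, nrow(at)))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("could not write PDB file: ", path)
  invisible(path)
}

#' Construct a DecoySet
#'
#' @param models list of [structure_model()] objects with unique ids.
#' @param target_id target identifier.
#' @param native optional native [structure_model()].
#' @param sequence optional target sequence; inferred from the models when
#'   omitted (majority residue at each index, "X" where uncovered).
#' @return object of class `DecoySet`.
#' @export
decoy_set <- function(models, target_id = "target", native = NULL,
                      sequence = NULL) {
  if (length(models) == 0L) stop("a DecoySet needs at least one model")
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate model ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids
  if (is.null(sequence)) sequence <- infer_sequence(models)
  len <- nchar(sequence)
  for (m in models) {
    ri <- residue_indices(m)
    if (max(ri) > len)
      stop("model '", m$model_id, "' has residue indices beyond the ",
           "target sequence length ", len)
  }
  structure(list(target_id = target_id, sequence = sequence,
                 models = models, native = native),
            class = "DecoySet")
}

#' @export
print.DecoySet <- function(x, ...) {
  cat("<DecoySet>", x$target_id, "-", length(x$models), "models, sequence length",
      nchar(x$sequence), if (!is.null(x$native)) "(native present)" else "", "\n")
  invisible(x)
}

infer_sequence <- function(models) {
  len <- max(vapply(models, function(m) max(residue_indices(m)), numeric(1)))
  votes <- matrix(0L, nrow = len, ncol = 21,
                  dimnames = list(NULL, c(names(AA1), "X")))
  for (m in models) {
    aa <- residue_aa(m)
    idx <- as.integer(names(aa))
    for (k in seq_along(idx)) {
      votes[idx[k], aa[k]] <- votes[idx[k], aa[k]] + 1L
    }
  }
  seq_chars <- apply(votes, 1, function(v) {
    if (sum(v) == 0L) return("X")
    if (sum(v == max(v)) > 1L) names(v)[which.max(v)] else names(v)[which.max(v)]
  })
  conflicts <- apply(votes, 1, function(v) sum(v > 0L) > 1L)
  if (any(conflicts))
    warning(sum(conflicts), " residue position(s) with inconsistent amino ",
            "acids across models; majority rule applied")
  paste(seq_chars, collapse = "")
}

#' Load a decoy set from a list-of-paths file
#'
#' The list file contains one model path per line; blank lines and lines
#' starting with `#` are ignored. Relative paths are resolved against the
#' directory of the list file. All listed paths must exist; files that
#' exist but fail to parse are skipped with a warning (their count is
#' recorded in the `n_skipped` attribute).
#'
#' @param list_file path to the list file.
#' @param native optional path to the native structure.
#' @param target_id target identifier; default is the list-file name.
#' @return a [decoy_set()] with models in file order.
#' @export
load_decoy_set <- function(list_file, native = NULL, target_id = NULL) {
  if (!file.exists(list_file)) stop("list file not found: ", list_file)
  lines <- trimws(readLines(list_file, warn = FALSE))
  paths <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(paths) == 0L) stop("list file '", list_file, "' names no models")
  rel <- !file.exists(paths)
  paths[rel] <- file.path(dirname(list_file), paths[rel])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing model file(s): ", paste(missing, collapse = ", "))
  models <- list()
  skipped <- character()
  for (p in paths) {
    m <- tryCatch(read_pdb(p), error = function(e) {
      warning("skipping unreadable model '", p, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(m)) models[[length(models) + 1L]] <- m else skipped <- c(skipped, p)
  }
  if (length(models) == 0L)
    stop("no valid models could be read from '", list_file, "'")
  ids <- vapply(models, function(m) m$model_id, character(1))
  ids <- make.unique(ids, sep = "_")
  for (k in seq_along(models)) models[[k]]$model_id <- ids[k]
  if (is.null(target_id))
    target_id <- sub("\\.[^.]*$", "", basename(list_file))
  native_model <- if (!is.null(native)) read_pdb(native) else NULL
  ds <- decoy_set(models, target_id = target_id, native = native_model)
  attr(ds, "n_skipped") <- length(skipped)
  attr(ds, "skipped_paths") <- skipped
  attr(ds, "input_paths") <- setNames(paths[!(paths %in% skipped)], ids)
  ds
}
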