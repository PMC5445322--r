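# Knowledge-based energy features: a trainable distance-dependent
# all-atom pair potential with a DFIRE-style reference state, and a
# backbone (phi, psi) torsion potential.  Both use the inverse-Boltzmann
# log-ratio form with kT folded into the (dimensionless) energy units;
# absolute scale is irrelevant because the ranker learns feature weights.

#' @name pair_potential
#' @title Distance-dependent pair potential
#' @description
#' Energies are `-ln((N_obs + p) / (N_exp + p))` per type pair and
#' distance bin, where the expected count is scaled down from the
#' outermost (cutoff) bin by the DFIRE-style reference state
#' `(r / r_cut)^alpha`. Atom typing is either `"full"` (167
#' residue-specific heavy-atom classes) or `"ca"` (20 residue classes on
#' CA atoms only, a fast reduced mode). Pairs within one residue and
#' backbone-backbone pairs of sequence-adjacent residues are excluded.
NULL

pair_config <- function(mode = c("ca", "full"), r_cut = 14.5, dr = 0.5,
                        alpha = 1.61, pseudocount = 0.5) {
  mode <- match.arg(mode)
  stopifnot(r_cut > 0, dr > 0, r_cut > dr)
  breaks <- seq(0, r_cut, by = dr)
  if (abs(breaks[length(breaks)] - r_cut) > 1e-9)
    breaks <- c(breaks, r_cut)
  types <- if (mode == "full") heavy_atom_types() else names(AA3)
  list(mode = mode, r_cut = r_cut, dr = dr, alpha = alpha,
       pseudocount = pseudocount, breaks = breaks, types = types)
}

# atom type labels for the heavy atoms of a model (NA = untyped)
atom_types_of <- function(atoms, mode) {
  res3 <- aa1to3(atoms$aa)
  if (mode == "ca") {
    out <- ifelse(atoms$elety == "CA", res3, NA_character_)
  } else {
    out <- paste(res3, atoms$elety, sep = ".")
  }
  out[!(out %in% if (mode == "ca") names(AA3) else heavy_atom_types())] <- NA_character_
  out
}

# Heavy-atom pairs of one model within r_cut, with exclusions applied.
# method "cell" bins atoms into an r_cut grid and only scans neighboring
# cells; "brute" is the exhaustive O(N^2) double loop used as the oracle.
model_pairs <- function(model, r_cut, method = c("cell", "brute")) {
  method <- match.arg(method)
  at <- heavy_atoms(model)
  n <- nrow(at)
  if (n < 2) return(data.frame(i = integer(), j = integer(), d = numeric()))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (method == "brute") {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  } else {
    cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / r_cut)
    dims <- apply(cell, 2, max) + 1L
    key <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
    by_cell <- split(seq_len(n), key)
    ckey <- as.numeric(names(by_cell))
    cz <- floor(ckey / (dims[1] * dims[2]))
    cy <- floor((ckey - cz * dims[1] * dims[2]) / dims[1])
    cx <- ckey - cz * dims[1] * dims[2] - cy * dims[1]
    lookup <- new.env(hash = TRUE)
    for (k in seq_along(ckey)) assign(as.character(ckey[k]), by_cell[[k]], lookup)
    i_all <- j_all <- integer(0)
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    for (k in seq_along(ckey)) {
      a_idx <- by_cell[[k]]
      for (o in seq_len(nrow(offs))) {
        nx <- cx[k] + offs$dx[o]; ny <- cy[k] + offs$dy[o]; nz <- cz[k] + offs$dz[o]
        if (nx < 0 || ny < 0 || nz < 0 || nx >= dims[1] || ny >= dims[2] || nz >= dims[3]) next
        nkey <- as.character(nx + dims[1] * (ny + dims[2] * nz))
        if (!exists(nkey, lookup, inherits = FALSE)) next
        b_idx <- get(nkey, lookup, inherits = FALSE)
        pm <- expand.grid(i = a_idx, j = b_idx)
        pm <- pm[pm$i < pm$j, , drop = FALSE]
        i_all <- c(i_all, pm$i); j_all <- c(j_all, pm$j)
      }
    }
    if (length(i_all) == 0L)
      return(data.frame(i = integer(), j = integer(), d = numeric()))
    dup <- duplicated(paste(i_all, j_all))
    i <- i_all[!dup]; j <- j_all[!dup]
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  }
  keep <- d < r_cut & d > 0
  # exclusions: same residue; adjacent-residue backbone-backbone contacts
  same_res <- at$resno[i] == at$resno[j]
  adj_bb <- abs(at$resno[i] - at$resno[j]) == 1L &
    at$elety[i] %in% BACKBONE_ATOMS & at$elety[j] %in% BACKBONE_ATOMS
  keep <- keep & !same_res & !adj_bb
  data.frame(i = i[keep], j = j[keep], d = d[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accumulate observed pair counts of one model into a counts array
accumulate_counts <- function(counts, model, cfg) {
  at <- heavy_atoms(model)
  prs <- model_pairs(model, cfg$r_cut)
  if (nrow(prs) == 0L) return(counts)
  ti <- atom_types_of(at, cfg$mode)[prs$i]
  tj <- atom_types_of(at, cfg$mode)[prs$j]
  ok <- !is.na(ti) & !is.na(tj)
  if (!any(ok)) return(counts)
  bin <- findInterval(prs$d[ok], cfg$breaks, rightmost.closed = FALSE)
  a <- match(ti[ok], cfg$types); b <- match(tj[ok], cfg$types)
  lo <- pmin(a, b); hi <- pmax(a, b)
  tab <- table(paste(lo, hi, bin))
  parts <- do.call(rbind, strsplit(names(tab), " "))
  idx <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]),
               as.integer(parts[, 3]))
  counts[idx] <- counts[idx] + as.integer(tab)
  counts
}

# inverse-Boltzmann energies from a counts array (types x types x bins)
pair_potential_from_counts <- function(counts, cfg) {
  nt <- length(cfg$types)
  nb <- length(cfg$breaks) - 1L
  stopifnot(dim(counts)[1] == nt, dim(counts)[3] == nb)
  mids <- (cfg$breaks[-1] + cfg$breaks[-length(cfg$breaks)]) / 2
  ref_ratio <- (mids / mids[nb])^cfg$alpha
  energies <- array(0, dim = c(nt, nt, nb),
                    dimnames = list(cfg$types, cfg$types, NULL))
  p <- cfg$pseudocount
  n_empty <- 0L
  for (a in seq_len(nt)) for (b in a:nt) {
    obs <- counts[a, b, ]
    if (all(obs == 0)) { n_empty <- n_empty + 1L; next }
    nexp <- counts[a, b, nb] * ref_ratio
    e <- -log((obs + p) / (nexp + p))
    e[!is.finite(e)] <- 0
    energies[a, b, ] <- e
    energies[b, a, ] <- e
  }
  if (n_empty > 0L)
    warning(n_empty, " atom type pair(s) had no observed contacts; ",
            "their energies are 0")
  structure(list(atom_types = cfg$types, breaks = cfg$breaks,
                 energies = energies, alpha = cfg$alpha,
                 pseudocount = cfg$pseudocount, r_cut = cfg$r_cut,
                 dr = cfg$dr, mode = cfg$mode),
            class = "PairPotential")
}

#' Train the distance-dependent pair potential
#'
#' Counts heavy-atom pair distances over the training structures and
#' converts them to inverse-Boltzmann energies against a DFIRE-style
#' reference state (see [pair_potential]).
#'
#' @param structures list of [structure_model()] objects (>= 1).
#' @param mode `"ca"` (20 residue classes, CA only; fast) or `"full"`
#'   (167 residue-specific heavy-atom classes).
#' @param r_cut distance cutoff in Angstrom.
#' @param dr bin width in Angstrom.
#' @param alpha reference-state exponent.
#' @param pseudocount smoothing count added to observed and expected.
#' @return object of class `PairPotential`.
#' @export
train_pair_potential <- function(structures, mode = c("ca", "full"),
                                 r_cut = 14.5, dr = 0.5, alpha = 1.61,
                                 pseudocount = 0.5) {
  if (length(structures) == 0L) stop("no training structures given")
  cfg <- pair_config(match.arg(mode), r_cut, dr, alpha, pseudocount)
  nt <- length(cfg$types); nb <- length(cfg$breaks) - 1L
  counts <- array(0, dim = c(nt, nt, nb))
  for (m in structures) counts <- accumulate_counts(counts, m, cfg)
  # symmetrize the upper-triangular accumulation
  for (a in seq_len(nt)) for (b in seq_len(nt)) if (a > b)
    counts[a, b, ] <- counts[b, a, ]
  pair_potential_from_counts(counts, cfg)
}

#' Score a model with a trained pair potential
#'
#' Sums the binned energies of all non-hydrogen atom pairs closer than the
#' cutoff (same-residue and adjacent-backbone pairs excluded). Atoms whose
#' type is not in the potential are skipped and counted.
#'
#' @param model a [structure_model()] object.
#' @param potential a `PairPotential` from [train_pair_potential()].
#' @param method `"cell"` (neighbor-list, default) or `"brute"`
#'   (exhaustive double loop; identical result, used for verification).
#' @return an `EnergyFeature`: list with `name`, `value`, `n_skipped`.
#' @export
score_pair_potential <- function(model, potential, method = c("cell", "brute")) {
  method <- match.arg(method)
  at <- heavy_atoms(model)
  types <- atom_types_of(at, potential$mode)
  n_unknown <- sum(is.na(types) &
                     (potential$mode == "full" | at$elety == "CA"))
  prs <- model_pairs(model, potential$r_cut, method = method)
  value <- 0
  if (nrow(prs) > 0L) {
    ti <- types[prs$i]; tj <- types[prs$j]
    ok <- !is.na(ti) & !is.na(tj)
    if (any(ok)) {
      bin <- findInterval(prs$d[ok], potential$breaks, rightmost.closed = FALSE)
      a <- match(ti[ok], potential$atom_types)
      b <- match(tj[ok], potential$atom_types)
      value <- sum(potential$energies[cbind(a, b, bin)])
    }
  }
  if (n_unknown > 0L)
    warning(n_unknown, " atom(s) of unknown type skipped in pair scoring")
  structure(list(name = "pair_energy", value = value,
                 n_skipped = n_unknown),
            class = "EnergyFeature")
}

# --- backbone torsion potential -------------------------------------------

torsion_config <- function(bin_deg = 30, pseudocount = 0.5) {
  stopifnot(360 %% bin_deg == 0)
  breaks <- seq(-180, 180, by = bin_deg)
  list(bin_deg = bin_deg, breaks = breaks,
       nb = length(breaks) - 1L, pseudocount = pseudocount)
}

torsion_bin <- function(angle, breaks) {
  angle[angle >= 180] <- angle[angle >= 180] - 360
  findInterval(angle, breaks, rightmost.closed = TRUE)
}

torsion_potential_from_counts <- function(counts, cfg) {
  # counts: aa x phi-bin x psi-bin
  stopifnot(dim(counts)[2] == cfg$nb, dim(counts)[3] == cfg$nb)
  aa <- dimnames(counts)[[1]]
  energies <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  p <- cfg$pseudocount
  for (k in seq_along(aa)) {
    obs <- counts[k, , ]
    tot <- sum(obs)
    if (tot == 0) next
    nexp <- tot / (cfg$nb^2)
    e <- -log((obs + p) / (nexp + p))
    e[!is.finite(e)] <- 0
    energies[k, , ] <- e
  }
  structure(list(breaks = cfg$breaks, bin_deg = cfg$bin_deg,
                 energies = energies, pseudocount = p),
            class = "TorsionPotential")
}

#' Train the backbone torsion potential
#'
#' Accumulates per-amino-acid (phi, psi) counts on a square grid over
#' \[-180, 180)^2 and converts them to inverse-Boltzmann energies against
#' a uniform reference. Terminal residues (missing phi or psi) are
#' skipped.
#'
#' @param structures list of [structure_model()] objects.
#' @param bin_deg grid bin width in degrees (must divide 360).
#' @param pseudocount smoothing count.
#' @return object of class `TorsionPotential`.
#' @export
train_torsion_potential <- function(structures, bin_deg = 30,
                                    pseudocount = 0.5) {
  if (length(structures) == 0L) stop("no training structures given")
  cfg <- torsion_config(bin_deg, pseudocount)
  aa <- names(AA1)
  counts <- array(0, dim = c(length(aa), cfg$nb, cfg$nb),
                  dimnames = list(aa, NULL, NULL))
  for (m in structures) {
    tor <- backbone_dihedrals(m)
    ok <- !is.na(tor$phi) & !is.na(tor$psi) & tor$aa %in% aa
    if (!any(ok)) next
    bp <- torsion_bin(tor$phi[ok], cfg$breaks)
    bs <- torsion_bin(tor$psi[ok], cfg$breaks)
    ak <- match(tor$aa[ok], aa)
    for (r in seq_along(ak))
      counts[ak[r], bp[r], bs[r]] <- counts[ak[r], bp[r], bs[r]] + 1
  }
  torsion_potential_from_counts(counts, cfg)
}

#' Score a model with a trained torsion potential
#'
#' Sum of per-residue (phi, psi) bin energies. Residues with missing
#' backbone atoms or undefined flanking residues are skipped and counted.
#'
#' @param model a [structure_model()] object.
#' @param potential a `TorsionPotential`.
#' @return an `EnergyFeature` (list with `name`, `value`, `n_skipped`).
#' @export
score_torsion_potential <- function(model, potential) {
  tor <- backbone_dihedrals(model)
  aa <- dimnames(potential$energies)[[1]]
  ok <- !is.na(tor$phi) & !is.na(tor$psi) & tor$aa %in% aa
  value <- 0
  if (any(ok)) {
    bp <- torsion_bin(tor$phi[ok], potential$breaks)
    bs <- torsion_bin(tor$psi[ok], potential$breaks)
    ak <- match(tor$aa[ok], aa)
    value <- sum(potential$energies[cbind(ak, bp, bs)])
  }
  structure(list(name = "torsion_energy", value = value,
                 n_skipped = sum(!ok)),
            class = "EnergyFeature")
}

# --- persistence -----------------------------------------------------------

#' Save / load a potential as JSON
#'
#' Potentials are persisted as versioned JSON with their configuration so
#' trained features are reproducible across sessions.
#'
#' @param potential a `PairPotential` or `TorsionPotential`.
#' @param path JSON file path.
#' @return `path` (write) or the potential object (read).
#' @export
write_potential <- function(potential, path) {
  kind <- class(potential)[1]
  obj <- unclass(potential)
  obj$energy_dim <- dim(potential$energies)
  obj$energy_dimnames <- dimnames(potential$energies)
  if (kind == "PairPotential") {
    # the table is symmetric in (type_i, type_j): store the upper
    # triangle (incl. diagonal) per bin, column-major
    nt <- obj$energy_dim[1]; nb <- obj$energy_dim[3]
    ut <- upper.tri(matrix(0, nt, nt), diag = TRUE)
    obj$energies <- as.numeric(vapply(seq_len(nb), function(b)
      potential$energies[, , b][ut], numeric(sum(ut))))
    obj$energy_packing <- "upper_tri"
  } else {
    obj$energies <- as.numeric(obj$energies)
    obj$energy_packing <- "dense"
  }
  obj$kind <- kind
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  dn <- obj$energy_dimnames
  if (is.list(dn)) dn <- lapply(dn, function(x) if (length(x)) x else NULL)
  if (identical(obj$energy_packing, "upper_tri")) {
    nt <- obj$energy_dim[1]; nb <- obj$energy_dim[3]
    ut <- upper.tri(matrix(0, nt, nt), diag = TRUE)
    packed <- matrix(obj$energies, ncol = nb)
    energies <- array(0, dim = obj$energy_dim, dimnames = dn)
    for (b in seq_len(nb)) {
      m <- matrix(0, nt, nt)
      m[ut] <- packed[, b]
      m <- m + t(m) - diag(diag(m))
      energies[, , b] <- m
    }
  } else {
    energies <- array(obj$energies, dim = obj$energy_dim, dimnames = dn)
  }
  obj$energies <- energies
  obj$kind <- obj$format_version <- obj$energy_dim <- NULL
  obj$energy_dimnames <- obj$energy_packing <- NULL
  structure(obj, class = kind)
}
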