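# Synthetic structures and decoy sets with known quality structure, and
# planted-weight feature suites: every pipeline stage is testable without
# external downloads.  All generators are deterministic per seed.

# ideal backbone geometry (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
OMEGA <- 180

fold_dihedrals <- function(length, fold) {
  switch(fold,
         helix = list(phi = rep(-57, length), psi = rep(-47, length)),
         sheet = list(phi = rep(-139, length), psi = rep(135, length)),
         coil = {
           # random walk over the broad allowed regions
           region <- sample(c("a", "b", "p"), length, replace = TRUE,
                            prob = c(0.4, 0.4, 0.2))
           phi <- ifelse(region == "a", -63, ifelse(region == "b", -120, -75)) +
             runif(length, -25, 25)
           psi <- ifelse(region == "a", -42, ifelse(region == "b", 130, 150)) +
             runif(length, -25, 25)
           list(phi = phi, psi = psi)
         },
         stop("unknown fold: ", fold))
}

build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, OMEGA)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANGLE_N_CA_C, phi[i])
  }
  for (i in 1:n) {
    # carbonyl O in the peptide plane, anti to the next N
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

pseudo_cb <- function(N, CA, C) {
  n1 <- unit(N - CA); n2 <- unit(C - CA)
  bis <- unit(n1 + n2); perp <- unit(cross3(n1, n2))
  CA + 1.53 * (-0.619 * bis + 0.786 * perp)
}

#' Generate a synthetic native structure
#'
#' Builds a backbone (N, CA, C, O plus a pseudo-CB for non-glycine
#' residues) with ideal bond geometry from per-residue (phi, psi) angles:
#' an ideal alpha-helix, an extended beta-strand, or a self-avoiding
#' random coil walk. The sequence is drawn uniformly over the 20 amino
#' acids. Deterministic per seed.
#'
#' @param length number of residues (>= 5).
#' @param fold `"helix"`, `"sheet"` or `"coil"`.
#' @param seed RNG seed.
#' @param model_id identifier.
#' @return a [structure_model()].
#' @export
make_native <- function(length, fold = c("helix", "sheet", "coil"), seed = 1,
                        model_id = "native") {
  fold <- match.arg(fold)
  if (length < 5) stop("length must be >= 5")
  set.seed(seed)
  aa <- sample(names(AA1), length, replace = TRUE)
  for (attempt in 1:50) {
    tor <- fold_dihedrals(length, fold)
    bb <- build_backbone(tor$phi, tor$psi)
    # self-avoidance: non-adjacent CA pairs at least 3.5 A apart
    dmat <- as.matrix(dist(bb$CA))
    sep <- abs(row(dmat) - col(dmat))
    if (min(dmat[sep > 1]) >= 3.5) {
      atoms <- do.call(rbind, lapply(seq_len(length), function(i) {
        rows <- data.frame(
          resno = i, aa = aa[i],
          elety = c("N", "CA", "C", "O"),
          elesy = c("N", "C", "C", "O"),
          x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
          y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
          z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]),
          is_h = FALSE, stringsAsFactors = FALSE)
        if (aa[i] != "G") {
          cb <- pseudo_cb(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
          rows <- rbind(rows, data.frame(resno = i, aa = aa[i], elety = "CB",
                                         elesy = "C", x = cb[1], y = cb[2],
                                         z = cb[3], is_h = FALSE,
                                         stringsAsFactors = FALSE))
        }
        rows
      }))
      return(structure_model(atoms, model_id = model_id,
                             source_path = paste0("synthetic:", fold)))
    }
  }
  stop("could not build a self-avoiding ", fold, " chain of length ", length)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
           2 * (b * c_ + a * d), a^2 - b^2 + c_^2 - d^2, 2 * (c_ * d - a * b),
           2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 - b^2 - c_^2 + d^2),
         3, 3, byrow = TRUE)
}

# noise ladders emulating the two CASP evaluation regimes: "select20"
# spans the whole quality range (GDT_TS roughly 10-100), "best150"
# concentrates at high quality.
REGIME_LADDERS <- list(
  select20 = list(sigmas = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4.5, 7),
                  decoys_per_level = 2),
  best150 = list(sigmas = c(0.25, 0.5, 0.75, 1, 1.25),
                 decoys_per_level = 30))

#' Generate a decoy set of controlled quality spread
#'
#' Each decoy is the native with i.i.d. Gaussian coordinate noise at one
#' sigma of the ladder, optionally followed by a random rigid motion
#' (which leaves true quality unchanged). The per-decoy sigma is recorded
#' in the `sigmas` attribute.
#'
#' @param native a [structure_model()].
#' @param sigmas noise ladder in Angstrom; overridden by `regime`.
#' @param decoys_per_level decoys per ladder level.
#' @param regime optional preset: `"select20"` (20 decoys spanning the
#'   quality range) or `"best150"` (150 decoys concentrated at high
#'   quality).
#' @param rigid apply a random rigid motion to each decoy.
#' @param seed RNG seed.
#' @param target_id identifier for the resulting [decoy_set()].
#' @return a [decoy_set()] with the native attached.
#' @export
make_decoys <- function(native, sigmas = c(0.5, 2, 8), decoys_per_level = 1,
                        regime = NULL, rigid = TRUE, seed = 1,
                        target_id = "synthetic") {
  if (!is.null(regime)) {
    regime <- match.arg(regime, names(REGIME_LADDERS))
    sigmas <- REGIME_LADDERS[[regime]]$sigmas
    decoys_per_level <- REGIME_LADDERS[[regime]]$decoys_per_level
  }
  stopifnot(all(sigmas >= 0), decoys_per_level >= 1)
  set.seed(seed)
  models <- list()
  sig_rec <- numeric()
  k <- 0L
  for (li in seq_along(sigmas)) {
    for (d in seq_len(decoys_per_level)) {
      k <- k + 1L
      at <- native$atoms
      n <- nrow(at)
      xyz <- as.matrix(at[, c("x", "y", "z")]) +
        matrix(rnorm(3 * n, sd = sigmas[li]), n, 3)
      if (rigid) {
        xyz <- xyz %*% random_rotation()
        xyz <- sweep(xyz, 2, runif(3, -20, 20), "+")
      }
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      id <- sprintf("decoy_L%02d_%02d", li, d)
      models[[id]] <- structure_model(at, model_id = id,
                                      source_path = "synthetic:decoy")
      sig_rec[id] <- sigmas[li]
    }
  }
  ds <- decoy_set(models, target_id = target_id, native = native,
                  sequence = paste(residue_aa(native), collapse = ""))
  attr(ds, "sigmas") <- sig_rec
  ds
}

#' Planted-weight feature suite for ranker recovery tests
#'
#' Generates per-target feature tables with standard-normal features and
#' true qualities `q = X w* + noise`; the known weight vector makes exact
#' recovery testable.
#'
#' @param n_targets number of targets.
#' @param models_per_target models per target.
#' @param weights planted weight vector (its length sets the feature
#'   count).
#' @param noise_sd standard deviation of the additive quality noise.
#' @param seed RNG seed.
#' @return list with `tables` (list of `FeatureTable`), `truths` (list of
#'   named quality vectors) and `weights`.
#' @export
make_planted_feature_suite <- function(n_targets = 20, models_per_target = 50,
                                       weights = c(2, -1, 0.5, 1.5, -0.8),
                                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  p <- length(weights)
  cols <- sprintf("f%02d", seq_len(p))
  tables <- list(); truths <- list()
  for (t_ in seq_len(n_targets)) {
    tid <- sprintf("planted%02d", t_)
    ids <- sprintf("%s_m%03d", tid, seq_len(models_per_target))
    X <- matrix(rnorm(models_per_target * p), models_per_target, p,
                dimnames = list(ids, cols))
    q <- drop(X %*% weights) + rnorm(models_per_target, sd = noise_sd)
    ft <- structure(list(target_id = tid, model_ids = ids, features = X,
                         provenance = setNames(rep("native", p), cols)),
                    class = "FeatureTable")
    attr(ft, "norm") <- list(center = colMeans(X), scale = apply(X, 2, sd))
    tables[[tid]] <- ft
    truths[[tid]] <- setNames(q, ids)
  }
  list(tables = tables, truths = truths, weights = weights)
}
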