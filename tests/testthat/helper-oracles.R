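# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's computational paths: plain-R linear algebra, brute
# force enumeration and Monte Carlo.

# plain-R Kabsch fit (svd written out here, independent of the C++ core)
r_kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  s <- svd(t(Ac) %*% Bc)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Ac %*% R
  list(R = R, t = cb - ca %*% R,
       rmsd = sqrt(mean(rowSums((fitted - Bc)^2))))
}

# brute-force minimal RMSD via optimization over an Euler-angle
# parameterization with several restarts
oracle_rmsd <- function(A, B, restarts = 8) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Ac %*% rot(ang) - Bc)^2)))
  best <- Inf
  set.seed(99)
  for (r in seq_len(restarts)) {
    ang0 <- runif(3, -pi, pi)
    o <- optim(ang0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# exhaustive-seed GDT oracle: every contiguous window of every length
# >= 3 seeds an iterative superpose-and-count refinement
oracle_gdt <- function(model, reference, max_iter = 10) {
  pm <- decoyrank:::ca_xyz(model)
  pr <- decoyrank:::ca_xyz(reference)
  common <- intersect(rownames(pm), rownames(pr))
  P <- pm[common, , drop = FALSE]; Q <- pr[common, , drop = FALSE]
  n <- nrow(P); lref <- nrow(pr)
  thresholds <- c(1, 2, 4, 8)
  dist_after <- function(sel) {
    f <- r_kabsch(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
    moved <- sweep(P %*% f$R, 2, as.numeric(f$t), "+")
    sqrt(rowSums((moved - Q)^2))
  }
  best <- setNames(numeric(4), paste0("P", thresholds))
  for (ti in seq_along(thresholds)) {
    d <- thresholds[ti]
    bc <- 0
    seeds <- list(seq_len(n))
    for (L in 3:n) for (s in 1:(n - L + 1)) seeds[[length(seeds) + 1]] <- s:(s + L - 1)
    for (sel in seeds) {
      for (it in seq_len(max_iter)) {
        dd <- dist_after(sel)
        inl <- which(dd < d)
        bc <- max(bc, length(inl))
        if (length(inl) < 3 || identical(inl, sel)) break
        sel <- inl
      }
      if (bc == n) break
    }
    best[ti] <- 100 * bc / lref
  }
  list(value = mean(best), per_threshold = best)
}

# O(N^2) double-loop pair-potential score, written independently
oracle_pair_score <- function(model, pot) {
  at <- model$atoms[!model$atoms$is_h, ]
  types <- decoyrank:::atom_types_of(at, pot$mode)
  total <- 0
  n <- nrow(at)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.na(types[i]) || is.na(types[j])) next
    if (at$resno[i] == at$resno[j]) next
    if (abs(at$resno[i] - at$resno[j]) == 1 &&
        at$elety[i] %in% c("N", "CA", "C", "O") &&
        at$elety[j] %in% c("N", "CA", "C", "O")) next
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (d <= 0 || d >= pot$r_cut) next
    b <- findInterval(d, pot$breaks)
    a <- match(types[i], pot$atom_types); bb <- match(types[j], pot$atom_types)
    total <- total + pot$energies[a, bb, b]
  }
  total
}

# exhaustive positive-negative pair counting AUC
oracle_auc <- function(predicted, true, threshold = 50) {
  pos <- which(true >= threshold); neg <- which(true < threshold)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (predicted[i] > predicted[j]) 1 else
      if (predicted[i] == predicted[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# closed-form MCC from confusion counts
oracle_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Monte-Carlo SASA with random (not spiral) directions
oracle_mc_sasa <- function(model, probe = 1.4, n_points = 20000, seed = 42) {
  set.seed(seed)
  at <- model$atoms[!model$atoms$is_h, ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- decoyrank:::vdw_radius(at$elesy) + probe
  pts <- matrix(rnorm(3 * n_points), n_points, 3)
  pts <- pts / sqrt(rowSums(pts^2))
  total <- 0
  for (i in seq_len(nrow(at))) {
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      acc <- acc & rowSums(sweep(sp, 2, xyz[j, ])^2) > rad[j]^2
    }
    total <- total + 4 * pi * rad[i]^2 * mean(acc)
  }
  total
}

# exact accessible area of two overlapping spheres (radii expanded)
oracle_two_sphere_area <- function(r1, r2, d) {
  cap <- function(R, rother) {
    if (d >= R + rother) return(0)
    h <- R - (d^2 + R^2 - rother^2) / (2 * d)
    2 * pi * R * max(min(h, 2 * R), 0)
  }
  c(4 * pi * r1^2 - cap(r1, r2), 4 * pi * r2^2 - cap(r2, r1))
}
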