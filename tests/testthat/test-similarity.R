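test_that("kabsch recovers exact rigid motions", {
  A <- random_ca_trace(10, seed = 1)
  fit0 <- kabsch(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  R90 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% R90
  B <- sweep(B, 2, c(5, 0, 0), "+")
  fit <- kabsch(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R90, tolerance = 1e-9)
  expect_equal(A %*% fit$rotation + matrix(fit$translation, 10, 3, byrow = TRUE),
               B, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)
})

test_that("kabsch rmsd matches brute-force rotational optimization", {
  for (s in 1:3) {
    A <- matrix(rnorm(30, sd = 4), 10, 3)
    B <- matrix(rnorm(30, sd = 4), 10, 3)
    expect_equal(kabsch(A, B)$rmsd, oracle_rmsd(A, B), tolerance = 1e-4)
  }
})

test_that("kabsch input contracts hold", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "3 paired points")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch(line, line), "collinear")
})

test_that("GDT_TS is exact on identity and rigid transforms", {
  m <- make_ca_model(random_ca_trace(25, seed = 2))
  s <- gdt_ts(m, m)
  expect_equal(s$value, 100)
  expect_equal(unname(s$per_threshold), rep(100, 4))
  expect_equal(s$value, mean(s$per_threshold), tolerance = 1e-9)

  moved <- rigid_move(m, seed = 3)
  expect_equal(gdt_ts(moved, m)$value, 100, tolerance = 1e-6)
})

test_that("split-structure toy gives GDT_TS 50 (brute-force-verified)", {
  # 8 residues: first 4 coincide with the reference, last 4 shifted 20 A.
  # No single superposition can satisfy both groups at <= 8 A, so every
  # threshold fits exactly 4 of 8 residues.
  base <- random_ca_trace(8, seed = 4)
  model <- base
  model[5:8, 1] <- model[5:8, 1] + 20
  ref <- make_ca_model(base)
  mod <- make_ca_model(model)
  expect_equal(gdt_ts(mod, ref)$value, 50)
  expect_equal(oracle_gdt(mod, ref)$value, 50)
})

test_that("GDT_TS per-threshold fractions are monotone in the threshold", {
  for (s in 1:5) {
    ref <- make_ca_model(random_ca_trace(20, seed = s))
    noisy <- ref
    set.seed(100 + s)
    xyz <- as.matrix(noisy$atoms[, c("x", "y", "z")]) +
      matrix(rnorm(60, sd = 2.5), 20, 3)
    noisy$atoms$x <- xyz[, 1]; noisy$atoms$y <- xyz[, 2]; noisy$atoms$z <- xyz[, 3]
    pt <- gdt_ts(noisy, ref)$per_threshold
    expect_true(all(diff(unname(pt)) >= 0))
  }
})

test_that("GDT_TS degrades monotonically with coordinate noise", {
  ref <- make_ca_model(random_ca_trace(30, seed = 6))
  sigmas <- c(0.5, 2, 5)
  medians <- vapply(seq_along(sigmas), function(k) {
    vals <- vapply(1:20, function(r) {
      set.seed(1000 * k + r)
      noisy <- ref
      xyz <- as.matrix(ref$atoms[, c("x", "y", "z")]) +
        matrix(rnorm(90, sd = sigmas[k]), 30, 3)
      noisy$atoms$x <- xyz[, 1]; noisy$atoms$y <- xyz[, 2]; noisy$atoms$z <- xyz[, 3]
      gdt_ts(noisy, ref)$value
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(medians) < 0))
})

test_that("full-length superposition never beats the seeded search", {
  for (s in 1:5) {
    ref <- make_ca_model(random_ca_trace(18, seed = 20 + s))
    noisy <- ref
    set.seed(50 + s)
    xyz <- as.matrix(ref$atoms[, c("x", "y", "z")]) +
      matrix(rnorm(54, sd = 3), 18, 3)
    noisy$atoms$x <- xyz[, 1]; noisy$atoms$y <- xyz[, 2]; noisy$atoms$z <- xyz[, 3]
    P <- decoyrank:::ca_xyz(noisy); Q <- decoyrank:::ca_xyz(ref)
    f <- r_kabsch(P, Q)
    d <- sqrt(rowSums((sweep(P %*% f$R, 2, as.numeric(f$t), "+") - Q)^2))
    lower <- mean(vapply(c(1, 2, 4, 8), function(th) 100 * sum(d < th) / 18,
                         numeric(1)))
    expect_gte(gdt_ts(noisy, ref)$value + 1e-9, lower)
  }
})

test_that("missing model residues count against the reference denominator", {
  ref <- make_ca_model(random_ca_trace(20, seed = 8))
  partial <- ref
  partial$atoms <- partial$atoms[partial$atoms$resno <= 10, ]
  s <- gdt_ts(partial, ref)
  expect_equal(s$value, 50)       # 10 of 20 reference residues fittable
  expect_error(gdt_ts(ref, partial), NA)  # opposite direction still works
})

test_that("TM-score is 1 on identity and matches its formula", {
  m <- make_ca_model(random_ca_trace(30, seed = 9))
  expect_equal(tm_score(m, m)$value, 1, tolerance = 1e-9)
  expect_equal(tm_score(rigid_move(m, 11), m)$value, 1, tolerance = 1e-6)
  # every paired distance equal to d0 contributes exactly 1/2
  d0 <- decoyrank:::tm_d0(30)
  expect_equal(decoyrank:::tm_from_dist(rep(d0, 30), d0) / 30, 0.5)
  # short references fall back to fixed d0 with a warning
  short <- make_ca_model(random_ca_trace(10, seed = 10))
  expect_warning(tm_score(short, short), "d0 = 0.5")
})

test_that("TM-score matches the exhaustive-seed oracle on perturbed chains", {
  ref <- make_ca_model(random_ca_trace(50, seed = 12))
  noisy <- ref
  set.seed(13)
  xyz <- as.matrix(ref$atoms[, c("x", "y", "z")]) +
    matrix(rnorm(150, sd = 1.5), 50, 3)
  noisy$atoms$x <- xyz[, 1]; noisy$atoms$y <- xyz[, 2]; noisy$atoms$z <- xyz[, 3]
  got <- tm_score(noisy, ref)$value
  # oracle: all full windows of every length, same iteration rule
  P <- decoyrank:::ca_xyz(noisy); Q <- decoyrank:::ca_xyz(ref)
  d0 <- decoyrank:::tm_d0(50)
  best <- 0
  for (L in c(3:10, 25, 50)) for (s in seq_len(50 - L + 1)) {
    sel <- s:(s + L - 1)
    for (it in 1:10) {
      f <- r_kabsch(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
      d <- sqrt(rowSums((sweep(P %*% f$R, 2, as.numeric(f$t), "+") - Q)^2))
      best <- max(best, sum(1 / (1 + (d / d0)^2)))
      inl <- which(d < max(d0, 3.5))
      if (length(inl) < 3 || identical(inl, sel)) break
      sel <- inl
    }
  }
  expect_equal(got, best / 50, tolerance = 1e-3)
})

test_that("pairwise similarity matrices are consistent with per-pair calls", {
  nat <- make_native(25, "coil", seed = 14)
  ds <- make_decoys(nat, sigmas = c(0.5, 2), decoys_per_level = 2, seed = 15)
  mods <- ds$models
  M <- pairwise_similarity_matrix(mods)
  expect_equal(unname(diag(M)), rep(100, 4))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    expect_equal(M[i, j], gdt_ts(mods[[i]], mods[[j]])$value)
  }
  # identical models give an all-100 matrix
  M2 <- pairwise_similarity_matrix(list(mods[[1]], mods[[1]]))
  expect_equal(unname(M2), matrix(100, 2, 2))
})

test_that("residue-disjoint models are flagged missing, not zero", {
  a <- make_ca_model(random_ca_trace(12, seed = 16))
  b <- make_ca_model(random_ca_trace(12, seed = 17))
  b$atoms$resno <- b$atoms$resno + 20L
  b$model_id <- "shifted"
  c_ <- make_ca_model(random_ca_trace(12, seed = 18), model_id = "c")
  expect_warning(M <- pairwise_similarity_matrix(list(a, b, c_)), "missing")
  expect_true(all(is.na(M["shifted", c("toy", "c")])))
  expect_true(all(is.na(M[c("toy", "c"), "shifted"])))
  expect_false(anyNA(M[c("toy", "c"), c("toy", "c")]))
})
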