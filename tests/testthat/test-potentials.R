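test_that("energies vanish when observed counts equal the reference expectation", {
  cfg <- decoyrank:::pair_config("ca", r_cut = 10, dr = 1, alpha = 1.61,
                                 pseudocount = 0.5)
  nt <- length(cfg$types); nb <- length(cfg$breaks) - 1L
  mids <- (cfg$breaks[-1] + cfg$breaks[-length(cfg$breaks)]) / 2
  counts <- array(0, dim = c(nt, nt, nb))
  for (a in 1:nt) for (b in 1:nt)
    counts[a, b, ] <- 40 * (mids / mids[nb])^cfg$alpha
  pot <- decoyrank:::pair_potential_from_counts(counts, cfg)
  expect_equal(max(abs(pot$energies)), 0)
})

test_that("a doubled bin count gives -ln 2 with zero pseudocount", {
  cfg <- decoyrank:::pair_config("ca", r_cut = 10, dr = 1, alpha = 1.61,
                                 pseudocount = 0)
  nt <- length(cfg$types); nb <- length(cfg$breaks) - 1L
  mids <- (cfg$breaks[-1] + cfg$breaks[-length(cfg$breaks)]) / 2
  counts <- array(0, dim = c(nt, nt, nb))
  expected <- 100 * (mids / mids[nb])^cfg$alpha
  counts[1, 1, ] <- expected
  counts[1, 1, 3] <- 2 * expected[3]
  pot <- suppressWarnings(decoyrank:::pair_potential_from_counts(counts, cfg))
  expect_equal(pot$energies[1, 1, 3], -log(2))
  expect_equal(pot$energies[1, 1, 5], 0)
})

test_that("energy tables are symmetric under type-pair swap", {
  nats <- lapply(1:3, function(s) make_native(30, "coil", seed = s))
  pot <- suppressWarnings(train_pair_potential(nats, mode = "ca"))
  for (b in seq_len(dim(pot$energies)[3]))
    expect_equal(pot$energies[, , b], t(pot$energies[, , b]))
})

test_that("a two-atom toy scores its single bin energy and is rigid-invariant", {
  cfg <- decoyrank:::pair_config("ca", r_cut = 10, dr = 1)
  nt <- length(cfg$types); nb <- length(cfg$breaks) - 1L
  counts <- array(0, dim = c(nt, nt, nb))
  counts[, , nb] <- 1
  pot <- decoyrank:::pair_potential_from_counts(counts, cfg)
  # plant a known energy in the ALA-ALA 5.5 A bin
  a <- match("ALA", pot$atom_types)
  pot$energies[a, a, 6] <- -0.5
  toy <- make_ca_model(rbind(c(0, 0, 0), c(5.5, 0, 0)))
  toy$atoms$resno <- c(1L, 3L)  # non-adjacent: the pair is not excluded
  expect_equal(score_pair_potential(toy, pot)$value, -0.5)
  expect_equal(score_pair_potential(rigid_move(toy, 5), pot)$value, -0.5)
})

test_that("neighbor-list scoring equals the exhaustive double loop exactly", {
  nats <- lapply(1:4, function(s) make_native(25, "coil", seed = 40 + s))
  pot <- suppressWarnings(train_pair_potential(nats, mode = "ca"))
  for (s in 1:3) {
    m <- make_native(30, "coil", seed = 50 + s)
    cell <- score_pair_potential(m, pot, method = "cell")$value
    brute <- score_pair_potential(m, pot, method = "brute")$value
    expect_identical(cell, brute)
    expect_equal(cell, oracle_pair_score(m, pot))
  }
})

test_that("full-atom typing covers the 167 heavy-atom classes", {
  types <- decoyrank:::heavy_atom_types()
  expect_length(types, 167)
  m <- make_native(20, "coil", seed = 60)
  pot <- suppressWarnings(train_pair_potential(list(m), mode = "full"))
  expect_length(pot$atom_types, 167)
  sc <- score_pair_potential(m, pot)
  expect_true(is.finite(sc$value))
})

test_that("the trained potential separates compact from expanded conformers", {
  train <- lapply(1:20, function(s) make_native(35, "coil", seed = 100 + s))
  pot <- suppressWarnings(train_pair_potential(train, mode = "ca"))
  wins <- 0L
  for (s in 1:20) {
    m <- make_native(35, "coil", seed = 200 + s)
    expanded <- m
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, colMeans(xyz)) * 1.5, 2, colMeans(xyz), "+")
    expanded$atoms$x <- xyz[, 1]; expanded$atoms$y <- xyz[, 2]
    expanded$atoms$z <- xyz[, 3]
    e_compact <- score_pair_potential(m, pot)$value
    e_expanded <- score_pair_potential(expanded, pot)$value
    if (e_compact < e_expanded) wins <- wins + 1L
  }
  expect_gte(wins, 18)
})

test_that("uniform torsion counts give zero energies", {
  cfg <- decoyrank:::torsion_config(bin_deg = 45, pseudocount = 0.5)
  counts <- array(7, dim = c(20, cfg$nb, cfg$nb),
                  dimnames = list(names(decoyrank:::AA1), NULL, NULL))
  pot <- decoyrank:::torsion_potential_from_counts(counts, cfg)
  expect_equal(max(abs(pot$energies)), 0)
})

test_that("torsion score is the sum of per-residue bin energies", {
  helix <- make_native(10, "helix", seed = 3)
  pot <- train_torsion_potential(list(helix), bin_deg = 30)
  # force every populated bin to energy -1: score must be -(n scoreable)
  pot$energies[pot$energies != 0] <- 0
  tor <- decoyrank:::backbone_dihedrals(helix)
  ok <- !is.na(tor$phi) & !is.na(tor$psi)
  expect_equal(sum(ok), 8)  # terminal residues are skipped
  aa <- dimnames(pot$energies)[[1]]
  bp <- decoyrank:::torsion_bin(tor$phi[ok], pot$breaks)
  bs <- decoyrank:::torsion_bin(tor$psi[ok], pot$breaks)
  for (r in which(ok)) {
    pot$energies[match(tor$aa[r], aa),
                 decoyrank:::torsion_bin(tor$phi[r], pot$breaks),
                 decoyrank:::torsion_bin(tor$psi[r], pot$breaks)] <- -1
  }
  sc <- score_torsion_potential(helix, pot)
  expect_equal(sc$value, -8)
  expect_equal(sc$n_skipped, 2L)
  # rigid-motion invariance of the torsion feature
  expect_equal(score_torsion_potential(rigid_move(helix, 9), pot)$value, -8)
})

test_that("a helix-trained torsion potential prefers helices over coils", {
  train <- lapply(1:10, function(s) make_native(25, "helix", seed = 300 + s))
  pot <- train_torsion_potential(train, bin_deg = 30)
  wins <- 0L
  for (s in 1:20) {
    h <- make_native(25, "helix", seed = 400 + s)
    c_ <- make_native(25, "coil", seed = 400 + s)
    if (score_torsion_potential(h, pot)$value <
        score_torsion_potential(c_, pot)$value) wins <- wins + 1L
  }
  expect_gte(wins, 18)
})

test_that("potentials survive a JSON round-trip", {
  nats <- lapply(1:2, function(s) make_native(20, "coil", seed = 70 + s))
  pp <- suppressWarnings(train_pair_potential(nats, mode = "ca"))
  tp <- train_torsion_potential(nats)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_potential(pp, f1); write_potential(tp, f2)
  pp2 <- read_potential(f1); tp2 <- read_potential(f2)
  expect_s3_class(pp2, "PairPotential")
  expect_s3_class(tp2, "TorsionPotential")
  expect_equal(pp2$energies, pp$energies)
  expect_equal(tp2$energies, tp$energies)
  m <- make_native(20, "coil", seed = 80)
  expect_equal(score_pair_potential(m, pp2)$value,
               score_pair_potential(m, pp)$value)
  expect_equal(score_torsion_potential(m, tp2)$value,
               score_torsion_potential(m, tp)$value)
})
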