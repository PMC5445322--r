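test_that("secondary structure assignment recognizes ideal geometries", {
  helix <- make_native(12, "helix", seed = 1)
  ssh <- assign_secondary_structure(helix)
  expect_gte(sum(ssh$labels == "H"), 8)

  sheet <- make_native(12, "sheet", seed = 2)
  sse <- assign_secondary_structure(sheet)
  expect_gte(sum(sse$labels == "E"), 6)

  # degenerate single-residue model falls back to all-coil
  one <- make_ca_model(matrix(c(0, 0, 0), 1, 3))
  expect_warning(ss1 <- assign_secondary_structure(one), "all-coil")
  expect_equal(unname(ss1$labels), "C")
})

test_that("ss consistency features count position-wise agreement", {
  f <- ss_consistency_features("HHHCCC", "HHHCCC")
  expect_equal(unname(f), c(0.5, 0, 0.5, 1.0))
  expect_equal(f[["ss_total"]], f[["ss_H"]] + f[["ss_E"]] + f[["ss_C"]])

  expect_equal(unname(ss_consistency_features("HHHH", "EEEE")), rep(0, 4))

  f3 <- ss_consistency_features("HECHEC", "HECCCC")
  expect_equal(unname(f3), c(1 / 6, 1 / 6, 2 / 6, 4 / 6))

  expect_error(ss_consistency_features("HH", "HHH"), "lengths differ")
})

test_that("ss_total always equals the sum of per-element fractions", {
  set.seed(5)
  for (r in 1:20) {
    a <- paste(sample(c("H", "E", "C"), 30, TRUE), collapse = "")
    b <- paste(sample(c("H", "E", "C"), 30, TRUE), collapse = "")
    f <- ss_consistency_features(a, b)
    expect_equal(f[["ss_total"]], f[["ss_H"]] + f[["ss_E"]] + f[["ss_C"]])
  }
})

test_that("two-sphere SASA matches the exact analytic formula", {
  # two carbons 2.5 A apart; expanded radii 1.7 + 1.4 each
  toy <- make_ca_model(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  sa <- compute_sasa(toy, n_points = 2000)
  exact <- oracle_two_sphere_area(1.7 + 1.4, 1.7 + 1.4, 2.5)
  expect_equal(unname(sa$values), exact, tolerance = 0.02)
})

test_that("isolated-residue SASA matches Monte-Carlo and distance decouples", {
  ala <- make_native(5, "coil", seed = 3)
  res1 <- ala$atoms[ala$atoms$resno == 1, ]
  iso <- structure_model(res1, "iso")
  got <- sum(compute_sasa(iso, n_points = 500)$values)
  mc <- oracle_mc_sasa(iso, n_points = 20000)
  expect_equal(got, mc, tolerance = 0.05 * mc)

  # the same residue duplicated 100 A away occludes nothing
  res2 <- res1
  res2$resno <- 3L
  res2$x <- res2$x + 100
  pair <- structure_model(rbind(res1, res2), "pair")
  sa_pair <- compute_sasa(pair, n_points = 500)
  expect_equal(unname(sa_pair$values), rep(got, 2), tolerance = 1e-6)

  # a residue buried in a dense cluster loses surface
  cluster <- res1
  for (k in 1:6) {
    shell <- res1
    shell$resno <- k + 2L
    offs <- rbind(c(4, 0, 0), c(-4, 0, 0), c(0, 4, 0),
                  c(0, -4, 0), c(0, 0, 4), c(0, 0, -4))[k, ]
    shell$x <- shell$x + offs[1]; shell$y <- shell$y + offs[2]
    shell$z <- shell$z + offs[3]
    cluster <- rbind(cluster, shell)
  }
  buried <- compute_sasa(structure_model(cluster, "cluster"), n_points = 500)
  expect_lt(buried$values[["1"]], got)
})

test_that("sa agreement features match textbook formulas", {
  f <- sa_agreement_features(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))
  expect_equal(unname(f), c(1, 1))

  f2 <- sa_agreement_features(c(1, 0), c(0, 1))
  expect_equal(f2[["sa_cos"]], 0)

  x <- c(0.1, 0.4, 0.7); y <- c(0.2, 0.5, 0.6)
  f3 <- sa_agreement_features(x, y)
  pcc <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(f3[["sa_pcc"]], pcc)
  expect_equal(f3[["sa_cos"]], sum(x * y) / sqrt(sum(x^2) * sum(y^2)))

  # symmetry in the two arguments
  expect_equal(unname(sa_agreement_features(y, x)), unname(f3))

  expect_warning(fz <- sa_agreement_features(c(0.5, 0.5), c(0.1, 0.9)),
                 "zero-variance")
  expect_equal(fz[["sa_pcc"]], 0)
})

test_that("relative SASA uses the max-accessibility table and clamps", {
  v <- setNames(c(129, 64.5, 1000), 1:3)
  rel <- relative_sasa(v, c("A", "A", "G"))
  expect_equal(unname(rel$values), c(1, 0.5, 1.5))
})

test_that("prediction files parse in both dialects", {
  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# predicted", "HHHEEC", "CC"), plain)
  ss <- read_ss_prediction(plain)
  expect_equal(paste(ss$labels, collapse = ""), "HHHEECCC")

  horiz <- withr::local_tempfile(fileext = ".horiz")
  writeLines(c("Conf: 999999", "Pred: HHHGGB", "  AA: MKVLAT",
               "", "Conf: 99", "Pred: EC", "  AA: QR"), horiz)
  ss2 <- read_ss_prediction(horiz)
  expect_equal(paste(ss2$labels, collapse = ""), "HHHHHEEC")

  sa_file <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.1 0.5", "0.9"), sa_file)
  sa <- read_sa_prediction(sa_file)
  expect_equal(unname(sa$values), c(0.1, 0.5, 0.9))
})

test_that("external score tables merge, impute and reject duplicates", {
  nat <- make_native(20, "coil", seed = 4)
  ds <- make_decoys(nat, sigmas = c(0.5, 2), decoys_per_level = 5, seed = 5)
  ids <- names(ds$models)

  full <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(model_id = ids, scoreA = seq_along(ids),
                       scoreB = rev(seq_along(ids))), full, row.names = FALSE)
  m <- ingest_external_scores(full, ds)
  expect_equal(dim(m), c(10L, 2L))
  expect_equal(attr(m, "n_imputed"), 0L)
  expect_equal(m[ids[3], "scoreA"], 3)

  partial <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(model_id = ids[1:8], scoreA = 1:8), partial,
            row.names = FALSE)
  m2 <- ingest_external_scores(partial, ds)
  expect_equal(attr(m2, "n_imputed"), 2L)
  expect_equal(unname(m2[ids[9:10], "scoreA"]), rep(median(1:8), 2))

  dup <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(model_id = c(ids[1], ids[1]), scoreA = 1:2), dup,
            row.names = FALSE)
  expect_error(ingest_external_scores(dup, ds), ids[1])

  alien <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(model_id = c("x", "y"), scoreA = 1:2), alien,
            row.names = FALSE)
  expect_error(ingest_external_scores(alien, ds), "no overlapping")
})

test_that("feature tables have the documented shape and column order", {
  nat <- make_native(25, "coil", seed = 6)
  ds <- make_decoys(nat, sigmas = c(0.5, 3), decoys_per_level = 3, seed = 7,
                    target_id = "shape")
  models <- lapply(1:5, function(i) ds$models[[i]])
  ds5 <- decoy_set(models, target_id = "shape", native = nat)
  nats <- lapply(1:3, function(s) make_native(25, "coil", seed = 20 + s))
  pp <- suppressWarnings(train_pair_potential(nats, mode = "ca"))
  tp <- train_torsion_potential(nats)
  ss_pred <- assign_secondary_structure(nat)
  sa_pred <- relative_sasa(compute_sasa(nat),
                           decoyrank:::residue_aa(nat))
  ft <- build_feature_table(ds5, pp, tp, predicted_ss = ss_pred,
                            predicted_sa = sa_pred)
  expect_equal(dim(ft$features), c(5L, 8L))
  expect_equal(colnames(ft$features),
               c("pair_energy", "torsion_energy", "ss_H", "ss_E", "ss_C",
                 "ss_total", "sa_pcc", "sa_cos"))

  ext <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(model_id = names(ds5$models), e1 = 1:5, e2 = 5:1,
                       e3 = 0), ext, row.names = FALSE)
  ft2 <- build_feature_table(ds5, pp, tp, predicted_ss = ss_pred,
                             predicted_sa = sa_pred, external_files = ext)
  expect_equal(ncol(ft2$features), 11L)
  expect_match(unname(ft2$provenance[["e1"]]), "external:")
})

test_that("feature tables are order-equivariant in the models", {
  nat <- make_native(20, "coil", seed = 8)
  ds <- make_decoys(nat, sigmas = c(1, 4), decoys_per_level = 2, seed = 9,
                    target_id = "perm")
  nats <- lapply(1:2, function(s) make_native(20, "coil", seed = 30 + s))
  pp <- suppressWarnings(train_pair_potential(nats, mode = "ca"))
  tp <- train_torsion_potential(nats)
  ft <- build_feature_table(ds, pp, tp)
  perm <- c(3, 1, 4, 2)
  ds_perm <- decoy_set(ds$models[perm], target_id = "perm", native = nat)
  ft_perm <- build_feature_table(ds_perm, pp, tp)
  expect_equal(ft_perm$features, ft$features[perm, ])
})
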