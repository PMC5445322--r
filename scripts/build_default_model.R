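#!/usr/bin/env Rscript

# Rebuilds the packaged default scoring model (inst/extdata/default_*.json):
# potentials trained on synthetic native folds and a two-feature
# (pair_energy, torsion_energy) ranking model trained on synthetic decoy
# sets labeled by GDT_TS to their natives.  Run from the repository root
# after installing the package; fully deterministic.

library(decoyrank)

seed <- 20260901

natives <- c(
  lapply(1:8, function(s) make_native(60, "coil", seed = seed + s)),
  lapply(1:4, function(s) make_native(40, "helix", seed = seed + 100 + s)),
  lapply(1:4, function(s) make_native(40, "sheet", seed = seed + 200 + s)))

# 1 A bins for the shipped default: better-estimated from the compact
# synthetic training corpus and a smaller packaged file
pair_pot <- suppressWarnings(train_pair_potential(natives, mode = "ca", dr = 1))
torsion_pot <- train_torsion_potential(natives)

tables <- list(); truths <- list()
for (t_ in 1:8) {
  nat <- natives[[t_]]
  ds <- make_decoys(nat, regime = "select20", seed = seed + 300 + t_,
                    target_id = sprintf("train%02d", t_))
  ft <- build_feature_table(ds, pair_potential = pair_pot,
                            torsion_potential = torsion_pot)
  q <- vapply(ds$models, function(m) gdt_ts(m, nat)$value, numeric(1))
  tables[[ds$target_id]] <- ft
  truths[[ds$target_id]] <- setNames(q, names(ds$models))
}

pairs <- make_pairs(tables, truths, seed = seed)
model <- fit_rank_model(pairs, C = 1, seed = seed)
print(model)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_rank_model(model, "inst/extdata/default_rank_model.json")
write_potential(pair_pot, "inst/extdata/default_pair_potential.json")
write_potential(torsion_pot, "inst/extdata/default_torsion_potential.json")
cat("wrote inst/extdata/default_{rank_model,pair_potential,torsion_potential}.json\n")
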