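# Shared fixture builders.  Everything is generated in code; no binary
# data ships with the tests.

# CA-only model from an n x 3 coordinate matrix
make_ca_model <- function(coords, aa = NULL, model_id = "toy") {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  atoms <- data.frame(resno = seq_len(n), aa = aa, elety = "CA",
                      elesy = "C", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], is_h = FALSE,
                      stringsAsFactors = FALSE)
  structure_model(atoms, model_id = model_id, source_path = "test")
}

# random self-avoiding-ish CA trace (consecutive spacing ~3.8 A)
random_ca_trace <- function(n, seed) {
  set.seed(seed)
  coords <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- rnorm(3)
    coords[i, ] <- coords[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
  }
  coords
}

# apply a rigid motion (random rotation + translation) to a model
rigid_move <- function(model, seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  R <- matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
                2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
                2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
              3, 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2, runif(3, -30, 30), "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# minimal one-residue ALA PDB text (N, CA, C, O), optional extra H
write_minimal_pdb <- function(path, with_h = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.712   7.124  -4.922  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.602   7.304  -5.755  1.00  0.00           O")
  if (with_h)
    lines <- c(lines,
      "ATOM      5  H   ALA A   1      10.504   5.444  -6.884  1.00  0.00           H")
  writeLines(c(lines, "END"), path)
  path
}
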