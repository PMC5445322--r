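# Small 3-D geometry helpers shared by the torsion potential, the
# secondary-structure assigner and the synthetic backbone builder.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Dihedral angle defined by four points
#'
#' Returns the torsion angle p1-p2-p3-p4 in degrees in (-180, 180], using
#' the standard IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a fourth point D from three anchors A, B, C given the bond length
# |C-D|, the bond angle B-C-D (degrees) and the torsion A-B-C-D (degrees).
# Inverse of dihedral_angle: dihedral_angle(A, B, C, place_atom(...)) == tau.
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  as.numeric(C + m %*% d)
}

# phi/psi backbone dihedrals for every residue of a model; NA where the
# flanking residue or a backbone atom is absent.
backbone_dihedrals <- function(model) {
  at <- model$atoms[!model$atoms$is_h, , drop = FALSE]
  resnos <- sort(unique(at$resno))
  bb <- lapply(c("N", "CA", "C"), function(nm) {
    idx <- match(paste(resnos, nm), paste(at$resno, at$elety))
    cbind(at$x[idx], at$y[idx], at$z[idx])
  })
  names(bb) <- c("N", "CA", "C")
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  ok <- function(m, i) !is.na(m[i, 1])
  for (i in seq_len(n)) {
    if (i > 1 && resnos[i - 1] == resnos[i] - 1 &&
        ok(bb$C, i - 1) && ok(bb$N, i) && ok(bb$CA, i) && ok(bb$C, i)) {
      phi[i] <- dihedral_angle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    }
    if (i < n && resnos[i + 1] == resnos[i] + 1 &&
        ok(bb$N, i) && ok(bb$CA, i) && ok(bb$C, i) && ok(bb$N, i + 1)) {
      psi[i] <- dihedral_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
    }
  }
  data.frame(resno = resnos, aa = residue_aa(model)[as.character(resnos)],
             phi = phi, psi = psi, row.names = NULL)
}
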