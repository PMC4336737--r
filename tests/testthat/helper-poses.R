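# constructors for synthetic enzyme-substrate poses with known geometry

# minimal enzyme: catalytic Cys (resno 25) with SG at the origin, an S2
# residue cluster around s2_center, an S1' cluster around s1p_center, and
# optional extra atoms used to bury substrate termini
make_test_enzyme <- function(s2_center = c(6, 0, 0), s1p_center = c(-6, 0, 0),
                             extra = NULL) {
  jitter3 <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 0.5, 0))
  atoms <- rbind(
    data.frame(resno = 25, resid = "CYS", elety = "SG",
               x = 0, y = 0, z = 0),
    data.frame(resno = 67, resid = "TRP", elety = c("CB", "CG", "CD1"),
               x = s2_center[1] + jitter3[, 1], y = s2_center[2] + jitter3[, 2],
               z = s2_center[3] + jitter3[, 3]),
    data.frame(resno = 140, resid = "ALA", elety = c("CB", "CA", "C"),
               x = s1p_center[1] + jitter3[, 1],
               y = s1p_center[2] + jitter3[, 2],
               z = s1p_center[3] + jitter3[, 3]))
  if (!is.null(extra)) atoms <- rbind(atoms, extra)
  atoms
}

# substrate tripeptide P2-P1-P1' (Phe-Arg-Phe-like) with controllable key
# atoms: P1 carbonyl C at p1c, P2 side chain at p2_side, P2 backbone N at
# nter, P1' atoms (incl. carboxyl C) at p1p
make_test_substrate <- function(p1c = c(0, 0, 3.5), p2_side = c(5.5, 0, 1),
                                nter = c(6, 2, 2), p1p = c(-5.5, 0, 1)) {
  rbind(
    data.frame(resno = 1, resid = "PHE", elety = "N", plabel = "P2",
               x = nter[1], y = nter[2], z = nter[3]),
    data.frame(resno = 1, resid = "PHE", elety = "CB", plabel = "P2",
               x = p2_side[1], y = p2_side[2], z = p2_side[3]),
    data.frame(resno = 2, resid = "ARG", elety = "C", plabel = "P1",
               x = p1c[1], y = p1c[2], z = p1c[3]),
    data.frame(resno = 3, resid = "PHE", elety = "C", plabel = "P1p",
               x = p1p[1], y = p1p[2], z = p1p[3]),
    data.frame(resno = 3, resid = "PHE", elety = "CB", plabel = "P1p",
               x = p1p[1], y = p1p[2] + 0.5, z = p1p[3]))
}

make_good_pose <- function(...) {
  make_pose(make_test_enzyme(...), make_test_substrate(),
            catalytic_cys = 25, s2_residues = 67, s1p_residues = 140)
}

# rigid-body motion: rotation about z by theta plus translation
apply_rigid <- function(atoms, theta = 0.7, shift = c(10, -3, 5)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}
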