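# Shared in-code fixtures; nothing is stored on disk.

# Hand-written 4-residue PDB with two heavy atoms per residue and B-factors
# 70, 80, 90, 60 (mean 75).
writeTinyPdb <- function(path) {
  fmt <- "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           %s"
  lines <- c(
    sprintf(fmt, 1, "N",  "ALA", 1, 0.0, 0.0, 0.0, 70, "N"),
    sprintf(fmt, 2, "CA", "ALA", 1, 1.5, 0.0, 0.0, 70, "C"),
    sprintf(fmt, 3, "N",  "GLY", 2, 3.0, 1.0, 0.0, 80, "N"),
    sprintf(fmt, 4, "CA", "GLY", 2, 4.5, 1.0, 0.5, 80, "C"),
    sprintf(fmt, 5, "N",  "SER", 3, 6.0, 2.0, 1.0, 90, "N"),
    sprintf(fmt, 6, "CA", "SER", 3, 7.5, 2.0, 1.5, 90, "C"),
    sprintf(fmt, 7, "N",  "LEU", 4, 9.0, 3.0, 2.0, 60, "N"),
    sprintf(fmt, 8, "CA", "LEU", 4, 10.5, 3.0, 2.5, 60, "C"),
    "END")
  writeLines(lines, path)
  path
}

# Same model as a minimal mmCIF.
writeTinyCif <- function(path) {
  atoms <- list(
    c(1, "N",  "ALA", 1, 0.0, 0.0, 0.0, 70, "N"),
    c(2, "CA", "ALA", 1, 1.5, 0.0, 0.0, 70, "C"),
    c(3, "N",  "GLY", 2, 3.0, 1.0, 0.0, 80, "N"),
    c(4, "CA", "GLY", 2, 4.5, 1.0, 0.5, 80, "C"),
    c(5, "N",  "SER", 3, 6.0, 2.0, 1.0, 90, "N"),
    c(6, "CA", "SER", 3, 7.5, 2.0, 1.5, 90, "C"),
    c(7, "N",  "LEU", 4, 9.0, 3.0, 2.0, 60, "N"),
    c(8, "CA", "LEU", 4, 10.5, 3.0, 2.5, 60, "C"))
  hdr <- c("data_tiny", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(atoms, function(a)
    sprintf("ATOM %s %s %s . %s A 1 %s ? %.3f %.3f %.3f 1.00 %.2f ? %s %s A %s 1",
            a[1], a[9], a[2], a[3], a[4], as.numeric(a[5]), as.numeric(a[6]),
            as.numeric(a[7]), as.numeric(a[8]), a[4], a[3], a[2]),
    character(1))
  writeLines(c(hdr, rows, "#"), path)
  path
}

# dense-discretization Gaussian linking oracle for an idealized circle+line
# geometry: both curves resampled at `n` points, full double sum (no window
# exclusions) -- an independent estimate of the true linking of the geometry.
denseLinkingOracle <- function(loopPts, tailPts, n = 1500) {
  densify <- function(p, n) {
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    t(vapply(seq(0, max(s), length.out = n), function(si) {
      k <- max(which(s <= si + 1e-12)); k <- min(k, nrow(p) - 1)
      f <- (si - s[k]) / (s[k + 1] - s[k])
      p[k, ] + f * (p[k + 1, ] - p[k, ])
    }, numeric(3)))
  }
  a <- densify(loopPts, n); b <- densify(tailPts, n)
  Ra <- (a[-1, ] + a[-nrow(a), ]) / 2; dRa <- diff(a)
  Rb <- (b[-1, ] + b[-nrow(b), ]) / 2; dRb <- diff(b)
  g <- 0
  for (m in seq_len(nrow(Rb))) {
    d <- sweep(Ra, 2, Rb[m, ], "-") * -1
    r3 <- (rowSums(d^2))^1.5
    cr <- cbind(dRb[m, 2] * dRa[, 3] - dRb[m, 3] * dRa[, 2],
                dRb[m, 3] * dRa[, 1] - dRb[m, 1] * dRa[, 3],
                dRb[m, 1] * dRa[, 2] - dRb[m, 2] * dRa[, 1])
    g <- g + sum(rowSums(d * cr) / r3)
  }
  g / (4 * pi)
}

# rigid rotation helper
randomRotation <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Rx %*% Rz
}

# the 40-residue folding fixture and its Go model (Calpha-proxy 8 A contacts,
# the calibrated default well depth)
goFixture <- function() {
  s <- genMiniProtein("helix_hairpin", seed = 1)$structure
  cm <- heavyAtomContacts(s, cutoff = 8)
  list(structure = s, contacts = cm, model = buildGoModel(s, cm))
}
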