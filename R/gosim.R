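#' Build a Calpha structure-based (Go-type) model
#'
#' The canonical Calpha Go recipe: harmonic bonds (k = 50 kcal/mol/A^2) and
#' angles (k = 30 kcal/mol/rad^2) at their native values, 1- and 3-fold
#' cosine dihedrals around the native torsion, a 12-10 Lennard-Jones well of
#' uniform depth \code{eps} on every native contact pair at its native
#' Calpha-Calpha distance, and a purely repulsive r^-12 excluded volume
#' (sigma = 4 A) between all other pairs separated by more than three
#' residues. The default \code{eps} is calibrated so the packaged 40-residue
#' fixture folds at 300 K while unfolding at 600 K.
#'
#' @param structure a \linkS4class{ProteinStructure} (>= 5 residues,
#'   gap-free Calpha trace).
#' @param contactMap a \linkS4class{ContactMap}; its pairs become the native
#'   wells.
#' @param eps native-well depth, kcal/mol.
#' @param bondK,angleK force constants.
#' @param dihedralK1,dihedralK3 cosine dihedral amplitudes.
#' @param repSigma,repEps excluded-volume parameters.
#' @return A \linkS4class{GoModel}.
#' @export
buildGoModel <- function(structure, contactMap, eps = 0.8, bondK = 50,
                         angleK = 30, dihedralK1 = 1.0, dihedralK3 = 0.5,
                         repSigma = 4.0, repEps = 1.0) {
  ca <- caCoords(structure)
  n <- nrow(ca)
  if (n < 5) stop("chain must have at least 5 residues")
  d <- function(i, j) sqrt(sum((ca[i, ] - ca[j, ])^2))
  bonds <- t(vapply(seq_len(n - 1), function(i)
    c(i, i + 1, d(i, i + 1), bondK), numeric(4)))
  angles <- t(vapply(seq_len(n - 2), function(i) {
    v1 <- ca[i, ] - ca[i + 1, ]; v2 <- ca[i + 2, ] - ca[i + 1, ]
    th <- acos(max(-1, min(1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2)))))
    c(i, i + 1, i + 2, th, angleK)
  }, numeric(5)))
  phis <- dihedralAngles(ca)
  dihedrals <- t(vapply(seq_len(n - 3), function(i)
    c(i, i + 1, i + 2, i + 3, phis[i], dihedralK1, dihedralK3),
    numeric(7)))
  cc <- contacts(contactMap)
  pairs <- if (nrow(cc) == 0) matrix(numeric(0), 0, 4) else
    t(vapply(seq_len(nrow(cc)), function(r)
      c(cc[r, 1], cc[r, 2], d(cc[r, 1], cc[r, 2]), eps), numeric(4)))
  new("GoModel", n = as.integer(n), bonds = bonds, angles = angles,
      dihedrals = dihedrals, pairs = pairs, repEps = repEps,
      repSigma = repSigma, repMinSep = 3L, nativeCoords = ca)
}

asCppModel <- function(model) {
  list(n = model@n, bonds = model@bonds, angles = model@angles,
       dihedrals = model@dihedrals, pairs = model@pairs,
       rep_eps = model@repEps, rep_sigma = model@repSigma,
       rep_min_sep = model@repMinSep)
}

#' Potential energy and forces of a Go model
#'
#' @param model a \linkS4class{GoModel}.
#' @param coords n x 3 coordinates (defaults to the native coordinates).
#' @return list with \code{energy} (kcal/mol) and \code{forces} (n x 3,
#'   kcal/mol/A).
#' @export
goEnergy <- function(model, coords = model@nativeCoords) {
  cpp_go_energy(asCppModel(model), as.matrix(coords))
}

#' Steepest-descent minimization
#'
#' @param model a \linkS4class{GoModel}.
#' @param coords starting coordinates.
#' @param nsteps iteration budget (default 100).
#' @param step0 initial step, Angstrom.
#' @return minimized n x 3 coordinates.
#' @export
goMinimize <- function(model, coords = model@nativeCoords, nsteps = 100,
                       step0 = 0.02) {
  cpp_go_minimize(asCppModel(model), as.matrix(coords), as.integer(nsteps),
                  step0)
}

#' Langevin dynamics leg
#'
#' BAOAB Langevin integration at a fixed temperature; \code{gammaPs = 0}
#' gives microcanonical velocity-Verlet dynamics (used by the
#' energy-conservation checks). Fully deterministic per seed.
#'
#' @param model a \linkS4class{GoModel}.
#' @param coords starting n x 3 coordinates.
#' @param nsteps number of steps.
#' @param dtFs time step, fs.
#' @param gammaPs friction, 1/ps.
#' @param tempK temperature, K.
#' @param seed integer RNG seed.
#' @param saveStride steps between saved frames (0 = save nothing).
#' @param mass bead mass, g/mol.
#' @param vel0 optional starting velocities (drawn from Maxwell-Boltzmann
#'   when NULL).
#' @return list: \code{frames} (list of n x 3 matrices), \code{temps}
#'   (kinetic temperature at each save), \code{etot} (total energy at each
#'   save), \code{coords}, \code{vel} (final state).
#' @export
goDynamics <- function(model, coords, nsteps, dtFs = 15, gammaPs = 0.05,
                       tempK = 300, seed = 1, saveStride = 5000,
                       mass = 110, vel0 = NULL) {
  if (nsteps == 0)
    return(list(frames = list(as.matrix(coords)), temps = numeric(0),
                etot = numeric(0), coords = as.matrix(coords), vel = NULL))
  res <- cpp_run_langevin(asCppModel(model), as.matrix(coords),
                          as.integer(nsteps), dtFs, gammaPs, tempK, mass,
                          as.integer(seed), as.integer(saveStride), vel0)
  n <- model@n
  frames <- lapply(seq_len(nrow(res$frames)), function(r)
    matrix(res$frames[r, ], ncol = 3, byrow = TRUE))
  list(frames = frames, temps = res$temps, etot = res$etot,
       coords = res$coords, vel = res$vel)
}

#' Construct a temperature-quench protocol
#'
#' Defaults follow the production protocol: 15 ns thermal unfolding at 600 K,
#' quench to 300 K, 15 fs time step, friction 0.05 1/ps, frames saved every
#' 5000 steps. The production scale (50 trajectories of 1.5 us) is
#' cluster-scale; the desk-scale defaults are 10 trajectories of 50 ns.
#'
#' @param tUnfoldNs unfolding-leg duration, ns.
#' @param tempUnfold,tempQuench leg temperatures, K.
#' @param dtFs time step, fs.
#' @param frictionPs Langevin friction, 1/ps.
#' @param nTraj number of independent trajectories.
#' @param tTrajNs quench-leg duration, ns.
#' @param saveStride steps between saved frames.
#' @return A \linkS4class{QuenchProtocol}.
#' @export
quenchProtocol <- function(tUnfoldNs = 15, tempUnfold = 600,
                           tempQuench = 300, dtFs = 15, frictionPs = 0.05,
                           nTraj = 10L, tTrajNs = 50, saveStride = 5000L) {
  new("QuenchProtocol", tUnfoldNs = tUnfoldNs, tempUnfold = tempUnfold,
      tempQuench = tempQuench, dtFs = dtFs, frictionPs = frictionPs,
      nTraj = as.integer(nTraj), tTrajNs = tTrajNs,
      saveStride = as.integer(saveStride))
}

#' Thermal-unfold / temperature-quench refolding run
#'
#' Each trajectory starts from the native coordinates, runs the unfolding leg
#' at the high temperature, then is quenched and run at the low temperature.
#' Trajectories are independent (seed + trajectory index) and the whole run
#' is reproducible per (model, protocol, seed).
#'
#' @param model a \linkS4class{GoModel}.
#' @param protocol a \linkS4class{QuenchProtocol}.
#' @param seed integer base seed.
#' @param mass bead mass, g/mol.
#' @return list of trajectories; each holds \code{unfold} and \code{quench}
#'   legs as returned by \code{\link{goDynamics}} plus \code{dtNsPerFrame}.
#' @export
runQuench <- function(model, protocol, seed = 1, mass = 110) {
  stepsUnfold <- round(protocol@tUnfoldNs * 1e6 / protocol@dtFs)
  stepsQuench <- round(protocol@tTrajNs * 1e6 / protocol@dtFs)
  lapply(seq_len(protocol@nTraj), function(t) {
    s <- seed * 1000L + t
    un <- goDynamics(model, model@nativeCoords, stepsUnfold,
                     dtFs = protocol@dtFs, gammaPs = protocol@frictionPs,
                     tempK = protocol@tempUnfold, seed = s,
                     saveStride = protocol@saveStride, mass = mass)
    qu <- goDynamics(model, un$coords, stepsQuench, dtFs = protocol@dtFs,
                     gammaPs = protocol@frictionPs,
                     tempK = protocol@tempQuench, seed = s + 500000L,
                     saveStride = protocol@saveStride, mass = mass,
                     vel0 = un$vel)
    list(unfold = un, quench = qu,
         dtNsPerFrame = protocol@dtFs * protocol@saveStride * 1e-6)
  })
}

# signed dihedral angles (radians) along a Calpha trace, length N-3
dihedralAngles <- function(ca) {
  n <- nrow(ca)
  vapply(seq_len(n - 3), function(i) {
    b1 <- ca[i + 1, ] - ca[i, ]
    b2 <- ca[i + 2, ] - ca[i + 1, ]
    b3 <- ca[i + 3, ] - ca[i + 2, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1])
    atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }, numeric(1))
}

#' Mirror-image trajectory heuristic
#'
#' A Calpha model cannot distinguish a structure from its mirror image
#' energetically except through the dihedral terms, and deep quenches can
#' trap the chain in the mirror basin. This heuristic flags a trajectory as
#' mirror-imaged when, over its final 10 percent of frames, the median
#' dihedral sign across natively helical segments (native dihedral between
#' 0.5 and 1.5 rad) is inverted relative to the native structure.
#'
#' @param frames list of n x 3 frame coordinate matrices.
#' @param structure the native \linkS4class{ProteinStructure}.
#' @return logical; FALSE with a warning when the native structure has no
#'   helical segments.
#' @export
mirrorFlag <- function(frames, structure) {
  ca <- caCoords(structure)
  phiN <- dihedralAngles(ca)
  helical <- which(phiN > 0.5 & phiN < 1.5)
  if (length(helical) == 0) helical <- which(phiN < -0.5 & phiN > -1.5)
  if (length(helical) == 0) {
    warning("no helical segments in the native structure; cannot assess ",
            "mirror symmetry")
    return(FALSE)
  }
  tail_frames <- frames[seq(max(1, ceiling(0.9 * length(frames))),
                            length(frames))]
  nativeSign <- median(sign(phiN[helical]))
  frameSign <- median(unlist(lapply(tail_frames, function(f)
    sign(dihedralAngles(f)[helical]))))
  is.finite(frameSign) && frameSign == -nativeSign
}
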