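#' Load a protein structure from PDB or mmCIF
#'
#' Reads a single-chain protein model, keeps heavy atoms only (altloc 'A' or
#' blank, HETATM ignored), drops residues lacking a Calpha atom (with a
#' warning), and renumbers residues 1..N preserving chain order so downstream
#' linking integrals operate on a gap-free trace. For AlphaFold models the
#' B-factor column holds per-residue pLDDT; set \code{plddtFromB = TRUE} to
#' read it.
#'
#' @param path file path.
#' @param format "pdb" or "mmcif"; guessed from the extension by default.
#' @param chain chain identifier; required when the file holds several chains.
#' @param plddtFromB logical; read per-residue pLDDT from the Calpha B-factor.
#' @return A \linkS4class{ProteinStructure}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeStructurePdb(genMiniProtein("helix_hairpin", seed = 1), pdb)
#' s <- loadStructure(pdb)
#' nResidues(s)
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          chain = NULL, plddtFromB = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- if (format == "mmcif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop("file has chains ", paste(chains, collapse = ", "),
           "; select one with `chain=`")
  } else {
    at <- at[at$chain == chain, , drop = FALSE]
    if (nrow(at) == 0) stop("chain ", chain, " not found")
  }
  # altloc: keep blank or 'A'
  if (!is.null(at$alt)) at <- at[at$alt %in% c("", "A", NA), , drop = FALSE]
  # hydrogen exclusion by element symbol, falling back to the atom name
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele)) || all(ele == "")) {
    ele <- sub("^[0-9]*", "", at$elety)
    ele <- substr(ele, 1, 1)
  }
  at <- at[!(toupper(ele) %in% c("H", "D")), , drop = FALSE]

  key <- paste(at$resno, at$insert %||% "", sep = "_")
  uk <- unique(key)
  newno <- match(key, uk)
  has_ca <- vapply(seq_along(uk), function(r)
    any(at$elety[newno == r] == "CA"), logical(1))
  if (!all(has_ca)) {
    warning(sum(!has_ca), " residue(s) lack a Calpha atom; dropped and ",
            "renumbered")
    keep <- has_ca[newno]
    at <- at[keep, , drop = FALSE]
    newno <- match(newno[keep], which(has_ca))
  }
  if (nrow(at) == 0 || !any(at$elety == "CA"))
    stop("structure has no residues with Calpha atoms")
  atoms <- data.frame(
    resno = as.integer(newno), resname = at$resid, elety = at$elety,
    element = if (!is.null(at$elesy)) at$elesy else substr(at$elety, 1, 1),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  caRows <- atoms$elety == "CA"
  ca <- as.matrix(atoms[caRows, c("x", "y", "z")])
  dimnames(ca) <- NULL
  pl <- numeric(0)
  if (plddtFromB) {
    if (is.null(at$b)) stop("no B-factor column to read pLDDT from")
    pl <- as.numeric(at$b[caRows])
  }
  if (!all(is.finite(ca))) stop("non-finite coordinates in ", path)
  new("ProteinStructure",
      id = sub("\\.[^.]*$", "", basename(path)),
      atoms = atoms, caCoords = ca, plddt = pl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a ProteinStructure from a Calpha trace
#'
#' Used by the synthetic generators and trajectory analysis: a chain given
#' only by Calpha coordinates, each residue carrying the single CA heavy atom.
#'
#' @param ca N x 3 coordinate matrix (Angstrom).
#' @param id protein identifier.
#' @param plddt optional per-residue scores.
#' @return A \linkS4class{ProteinStructure}.
#' @export
structureFromCa <- function(ca, id = "synthetic", plddt = numeric(0)) {
  ca <- as.matrix(ca)
  dimnames(ca) <- NULL
  n <- nrow(ca)
  atoms <- data.frame(resno = seq_len(n), resname = "GLY", elety = "CA",
                      element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      stringsAsFactors = FALSE)
  new("ProteinStructure", id = id, atoms = atoms, caCoords = ca,
      plddt = as.numeric(plddt))
}

#' Write a ProteinStructure to a PDB file
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructurePdb <- function(structure, path) {
  a <- structure@atoms
  b <- rep(0, nrow(a))
  if (length(structure@plddt) > 0) b <- structure@plddt[a$resno]
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  n <- nrow(a)
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   elety = a$elety, chain = rep("A", n), o = rep(1, n), b = b)
  invisible(path)
}

#' Mean-pLDDT quality gate
#'
#' TRUE iff the structure's mean per-residue pLDDT meets the threshold
#' (the proteome analysis keeps models with mean pLDDT >= 70).
#'
#' @param structure a \linkS4class{ProteinStructure} with pLDDT loaded.
#' @param threshold score threshold (default 70).
#' @return logical.
#' @export
meanPlddtPass <- function(structure, threshold = 70) {
  if (length(structure@plddt) == 0)
    stop("structure has no pLDDT scores (load with plddtFromB = TRUE)")
  mean(structure@plddt) >= threshold
}

#' Heavy-atom native contact map
#'
#' Two residues are in contact when they are separated by more than
#' \code{minSeqSep} residues along the sequence and any pair of their heavy
#' atoms lies within \code{cutoff} Angstrom (boundary inclusive).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param minSeqSep minimum sequence separation (default 3: pairs with
#'   |i - j| > 3 are eligible).
#' @return A \linkS4class{ContactMap}.
#' @export
heavyAtomContacts <- function(structure, cutoff = 4.5, minSeqSep = 3L) {
  a <- structure@atoms
  if (nrow(a) == 0) stop("empty structure")
  cc <- cpp_contact_map(as.matrix(a[, c("x", "y", "z")]),
                        as.integer(a$resno), cutoff, as.integer(minSeqSep))
  new("ContactMap", contacts = cc, cutoff = cutoff,
      minSeqSep = as.integer(minSeqSep))
}

#' Asphericity (relative shape anisotropy)
#'
#' Computed from the gyration-tensor eigenvalues l1 >= l2 >= l3 as
#' Delta = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2, which is 0 for a
#' sphere and 1 for a rod; the simulation-candidate filter uses Delta < 0.4.
#'
#' @param structure a \linkS4class{ProteinStructure} (>= 3 residues).
#' @return scalar in [0, 1].
#' @export
asphericity <- function(structure) {
  ca <- caCoords(structure)
  if (nrow(ca) < 3) stop("need at least 3 Calpha positions")
  cc <- sweep(ca, 2, colMeans(ca))
  S <- crossprod(cc) / nrow(ca)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(ev)
  if (tr^2 < 1e-20) return(0)  # all points coincide: spherical limit
  1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / tr^2
}

#' Write a contact map as TSV
#'
#' Columns \code{i}, \code{j}, \code{min_dist}.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeContactsTsv <- function(map, path) {
  write.table(as.data.frame(contacts(map)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
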