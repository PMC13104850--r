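#' Gaussian linking numbers of a loop against both terminal tails
#'
#' Discretizes the Calpha trace into segment midpoints R_l = (r_l + r_{l+1})/2
#' and bond vectors dR_l = r_{l+1} - r_l, then evaluates the double sum
#' g = (1/4 pi) sum_m sum_n (R_m - R_n)/|R_m - R_n|^3 . (dR_m x dR_n) with
#' loop segments n = i..j-1 and tail segments m = 6..i-5 (N tail) or
#' m = j+6..N-5 (C tail). The first and last five residues and five residues
#' flanking the loop are excluded by those summation limits; an empty tail
#' range yields exactly 0. The sign of g encodes threading chirality.
#'
#' @param ca N x 3 Calpha coordinate matrix (Angstrom).
#' @param loop integer pair (i, j), 1 <= i < j <= N.
#' @return named list with \code{loop}, \code{gN}, \code{gC}.
#' @examples
#' fx <- genLoopCurve(24, threaded = TRUE, seed = 1)
#' gaussLinking(caCoords(fx$structure), fx$loop)
#' @export
gaussLinking <- function(ca, loop) {
  ca <- as.matrix(ca)
  if (!all(is.finite(ca))) stop("non-finite coordinates")
  i <- as.integer(loop[1]); j <- as.integer(loop[2])
  if (i >= j) stop("loop must satisfy i < j")
  g <- cpp_gauss_link(ca, i, j)
  list(loop = c(i, j), gN = unname(g["gN"]), gC = unname(g["gC"]))
}

#' Cumulative partial linking profile along one tail
#'
#' The linking value accumulated after including tail segments up to each tail
#' residue, used to localize where the tail pierces the loop plane.
#'
#' @param ca N x 3 Calpha coordinates.
#' @param loop integer pair (i, j).
#' @param terminus "N" or "C".
#' @return numeric vector of cumulative g, with attribute \code{segment}
#'   giving the 1-based residue index of each included tail segment; length 0
#'   when the tail range is empty.
#' @export
partialLinkingProfile <- function(ca, loop, terminus = c("N", "C")) {
  terminus <- match.arg(terminus)
  prof <- cpp_partial_profile(as.matrix(ca), as.integer(loop[1]),
                              as.integer(loop[2]), terminus)
  if (length(prof) == 0) stop("empty ", terminus, " tail for this loop")
  prof
}

#' Locate loop-plane crossings from a partial linking profile
#'
#' A crossing is reported at each tail residue where the cumulative linking
#' value passes through a half-integer level k + 0.5 (equivalently where
#' round(g) changes), with the sign of the step.
#'
#' @param profile output of \code{\link{partialLinkingProfile}}.
#' @return data.frame with columns \code{residue} and \code{sign}; zero rows
#'   when the tail never crosses.
#' @export
findCrossings <- function(profile) {
  segs <- attr(profile, "segment")
  lev <- round(c(0, profile))
  d <- diff(lev)
  idx <- which(d != 0)
  if (length(idx) == 0)
    return(data.frame(residue = integer(0), sign = integer(0)))
  # a step crossing several half-integer levels reports one crossing per level
  res <- integer(0); sgn <- integer(0)
  for (k in idx) {
    m <- abs(d[k])
    res <- c(res, rep(segs[k], m))
    sgn <- c(sgn, rep(as.integer(sign(d[k])), m))
  }
  data.frame(residue = res, sign = sgn)
}

#' Slipknot detection on one tail
#'
#' A slipknot is a threading that retracts: the tail pierces the loop plane
#' and comes back out, producing crossings of opposite sign whose net
#' contribution cancels. Such tails are excluded from NCLE calls.
#'
#' @param crossings data.frame from \code{\link{findCrossings}} for one tail.
#' @param g the tail's full linking value (used to confirm the cancellation).
#' @return logical.
#' @export
isSlipknot <- function(crossings, g) {
  if (nrow(crossings) < 2) return(FALSE)
  any(crossings$sign > 0) && any(crossings$sign < 0)
}

#' Detect native non-covalent lasso entanglements
#'
#' Every native contact (i, j) is a candidate loop-closing contact; the loop
#' is called entangled when |gN| or |gC| reaches \code{threshold}. Each
#' entangled tail is annotated with its crossing residues; tails whose
#' crossings cancel (slipknots) are discarded, and a candidate with no
#' remaining entangled tail is dropped.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param contactMap a \linkS4class{ContactMap} from
#'   \code{\link{heavyAtomContacts}}.
#' @param threshold detection threshold on |g| (default 0.6).
#' @return list of \linkS4class{NCLE} objects (possibly empty).
#' @examples
#' s <- genMiniProtein("entangled_hairpin", seed = 1)$structure
#' detectNcles(s, heavyAtomContacts(s, minSeqSep = 3))
#' @export
detectNcles <- function(structure, contactMap, threshold = 0.6) {
  ca <- caCoords(structure)
  cc <- contacts(contactMap)
  if (nrow(cc) == 0) return(list())
  loops <- matrix(as.integer(cc[, 1:2]), ncol = 2)
  g <- cpp_gauss_link_batch(ca, loops)
  cand <- which(abs(g[, "gN"]) >= threshold | abs(g[, "gC"]) >= threshold)
  out <- list()
  for (k in cand) {
    i <- loops[k, 1]; j <- loops[k, 2]
    crs <- data.frame(residue = integer(0), sign = integer(0),
                      terminus = character(0))
    keep <- FALSE
    for (term in c("N", "C")) {
      gv <- if (term == "N") g[k, "gN"] else g[k, "gC"]
      if (abs(gv) < threshold) next
      prof <- cpp_partial_profile(ca, i, j, term)
      cr <- findCrossings(prof)
      if (isSlipknot(cr, gv)) next
      keep <- TRUE
      if (nrow(cr) > 0)
        crs <- rbind(crs, cbind(cr, terminus = term))
    }
    if (!keep) next
    out[[length(out) + 1]] <- new(
      "NCLE", loop = c(i, j), gN = unname(g[k, "gN"]), gC = unname(g[k, "gC"]),
      crossings = crs, representative = FALSE, clusterId = NA_integer_)
  }
  out
}

#' Cluster degenerate NCLEs and pick representatives
#'
#' A single threaded loop is typically closed by several neighbouring native
#' contacts, producing degenerate NCLE calls. Two NCLEs share a cluster when
#' they have the same number of crossings with identical signs and every
#' crossing residue agrees within +/-5 sequence positions (transitively).
#' The representative of each cluster is the member with the shortest loop
#' (smallest j - i), ties broken by the smallest i.
#'
#' @param ncles list of \linkS4class{NCLE} from one protein.
#' @return the same list with \code{clusterId} filled and exactly one
#'   \code{representative} per cluster.
#' @export
clusterNcles <- function(ncles) {
  n <- length(ncles)
  if (n == 0) return(ncles)
  same <- function(a, b) {
    ca <- a@crossings[order(a@crossings$residue), , drop = FALSE]
    cb <- b@crossings[order(b@crossings$residue), , drop = FALSE]
    nrow(ca) == nrow(cb) &&
      (nrow(ca) == 0 ||
         (all(ca$sign == cb$sign) && all(ca$terminus == cb$terminus) &&
            all(abs(ca$residue - cb$residue) <= 5)))
  }
  # union-find over pairwise matches
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1)
    for (a in seq_len(n - 1)) for (b in seq(a + 1, n))
      if (same(ncles[[a]], ncles[[b]])) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  for (k in seq_len(n)) {
    ncles[[k]]@clusterId <- ids[k]
    ncles[[k]]@representative <- FALSE
  }
  for (cl in unique(ids)) {
    mem <- which(ids == cl)
    len <- vapply(mem, function(k) diff(ncles[[k]]@loop), integer(1))
    i0 <- vapply(mem, function(k) ncles[[k]]@loop[1], integer(1))
    rep_k <- mem[order(len, i0)][1]
    ncles[[rep_k]]@representative <- TRUE
  }
  ncles
}

#' Entangled-region residue mask
#'
#' The entangled region of a protein is the union of (a) all residues within
#' +/-\code{buffer} sequence positions of any loop-closing contact residue or
#' crossing residue of a representative NCLE (clipped at the chain ends), and
#' (b) all residues with any heavy atom within \code{cutoff} Angstrom of
#' those key residues.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param ncles list of \linkS4class{NCLE}; only representatives are used
#'   (all members are used if none is flagged).
#' @param buffer sequence buffer (default 3).
#' @param cutoff spatial cutoff in Angstrom (default 4.5).
#' @return An \linkS4class{EntangledRegionMask}.
#' @export
entangledRegionMask <- function(structure, ncles, buffer = 3L, cutoff = 4.5) {
  n <- nResidues(structure)
  mask <- rep(FALSE, n)
  reps <- Filter(function(x) isTRUE(x@representative), ncles)
  if (length(reps) == 0) reps <- ncles
  key <- integer(0)
  for (nc in reps)
    key <- c(key, nc@loop, nc@crossings$residue)
  key <- sort(unique(key))
  if (length(key) == 0)
    return(new("EntangledRegionMask", proteinId = structure@id, mask = mask,
               sourceLoops = lapply(reps, function(x) x@loop)))
  for (r in key)
    mask[max(1L, r - buffer):min(n, r + buffer)] <- TRUE
  # spatial neighbours of the key residues (any heavy atom within cutoff)
  a <- structure@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  keyAtoms <- a$resno %in% key
  if (any(keyAtoms)) {
    kx <- xyz[keyAtoms, , drop = FALSE]
    for (r in setdiff(seq_len(n), which(mask))) {
      rx <- xyz[a$resno == r, , drop = FALSE]
      d2min <- min(vapply(seq_len(nrow(rx)), function(q)
        min(colSums((t(kx) - rx[q, ])^2)), numeric(1)))
      if (d2min <= cutoff^2) mask[r] <- TRUE
    }
  }
  new("EntangledRegionMask", proteinId = structure@id, mask = mask,
      sourceLoops = lapply(reps, function(x) x@loop))
}

#' Protein-level entanglement indicator
#'
#' TRUE iff the structure contains at least one NCLE (the binary exposure E
#' of the association analyses).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param threshold detection threshold on |g|.
#' @return logical.
#' @export
isEntangled <- function(structure, threshold = 0.6) {
  cm <- heavyAtomContacts(structure)
  length(detectNcles(structure, cm, threshold)) > 0
}

#' Write NCLE annotations as TSV
#'
#' One row per NCLE: protein, loop_i, loop_j, gN, gC, crossings (comma-joined
#' residue:sign), representative flag, cluster id.
#'
#' @param ncles list of \linkS4class{NCLE}.
#' @param proteinId character id written in the first column.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNclesTsv <- function(ncles, proteinId, path) {
  rows <- lapply(ncles, function(x) data.frame(
    protein = proteinId, loop_i = x@loop[1], loop_j = x@loop[2],
    gN = x@gN, gC = x@gC,
    crossings = paste(sprintf("%d:%+d", x@crossings$residue,
                              x@crossings$sign), collapse = ","),
    representative = as.integer(x@representative), cluster = x@clusterId,
    stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(0), loop_i = integer(0),
               loop_j = integer(0), gN = numeric(0), gC = numeric(0),
               crossings = character(0), representative = integer(0),
               cluster = integer(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a residue mask as TSV
#'
#' Columns protein, residue, in_region (0/1); the same joinable dialect is
#' used for entangled-region and proteolytic-alteration masks.
#'
#' @param mask an \linkS4class{EntangledRegionMask} or a logical vector.
#' @param proteinId protein id (taken from the object when omitted).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMaskTsv <- function(mask, path, proteinId = NULL) {
  if (is(mask, "EntangledRegionMask")) {
    proteinId <- proteinId %||% mask@proteinId
    mask <- mask@mask
  }
  df <- data.frame(protein = proteinId, residue = seq_along(mask),
                   in_region = as.integer(mask))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
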