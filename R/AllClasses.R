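#' @import methods
#' @importFrom stats coef fisher.test glm binomial quantile sd median pt
#'   kmeans p.adjust rnorm runif rbinom setNames t.test dist qnorm plogis
#' @importFrom utils read.table write.table
#' @useDynLib entangleAge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ProteinStructure: a single-chain protein model
#'
#' Holds per-atom heavy-atom coordinates grouped by residue, the Calpha trace,
#' and (optionally) per-residue pLDDT confidence scores read from the B-factor
#' column of AlphaFold models. Residues are renumbered 1..N in chain order at
#' load time so the linking integrals always see a gap-free trace.
#'
#' @slot id character protein identifier.
#' @slot atoms data.frame with columns \code{resno} (1-based residue index),
#'   \code{resname}, \code{elety} (atom name), \code{element}, \code{x},
#'   \code{y}, \code{z} (Angstrom). Heavy atoms only.
#' @slot caCoords numeric N x 3 matrix of Calpha coordinates (Angstrom).
#' @slot plddt numeric vector of per-residue scores in [0, 100], or length 0
#'   when absent.
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame",
                 caCoords = "matrix", plddt = "numeric"))

setValidity("ProteinStructure", function(object) {
  n <- nrow(object@caCoords)
  msg <- character()
  if (ncol(object@caCoords) != 3) msg <- c(msg, "caCoords must be N x 3")
  if (!all(is.finite(object@caCoords))) msg <- c(msg, "non-finite coordinates")
  r <- unique(object@atoms$resno)
  if (nrow(object@atoms) > 0 && !identical(as.integer(r), seq_len(n)))
    msg <- c(msg, "atom residue indices must be gap-free 1..N")
  if (length(object@plddt) > 0 && length(object@plddt) != n)
    msg <- c(msg, "plddt length must equal residue count")
  if (length(msg)) msg else TRUE
})

#' ContactMap: native heavy-atom contacts
#'
#' Residue pairs (i, j), i < j, separated by more than \code{minSeqSep}
#' positions along the sequence whose minimum heavy-atom distance is at most
#' \code{cutoff} Angstrom.
#'
#' @slot contacts numeric matrix with columns \code{i}, \code{j},
#'   \code{min_dist}.
#' @slot cutoff numeric distance cutoff (Angstrom).
#' @slot minSeqSep integer minimum sequence separation (pairs with
#'   |i - j| <= minSeqSep are excluded).
#' @exportClass ContactMap
setClass("ContactMap",
  representation(contacts = "matrix", cutoff = "numeric",
                 minSeqSep = "integer"))

setValidity("ContactMap", function(object) {
  cc <- object@contacts
  if (nrow(cc) == 0) return(TRUE)
  if (any(cc[, 1] >= cc[, 2])) return("contacts must satisfy i < j")
  if (any(cc[, 2] - cc[, 1] <= object@minSeqSep))
    return("contacts violate the minimum sequence separation")
  TRUE
})

#' NCLE: a non-covalent lasso entanglement
#'
#' A backbone loop closed by the native contact \code{loop = c(i, j)} and
#' pierced by a terminal tail. \code{gN}/\code{gC} are the discretized
#' Gaussian linking numbers between the loop and the N-/C-terminal tail;
#' \code{crossings} localizes where each tail pierces the loop plane.
#'
#' @slot loop integer length-2 vector (i, j), i < j.
#' @slot gN,gC numeric linking values.
#' @slot crossings data.frame with columns \code{residue}, \code{sign}
#'   (+1/-1), \code{terminus} ("N"/"C").
#' @slot representative logical; TRUE for the cluster representative.
#' @slot clusterId integer degenerate-NCLE cluster label.
#' @exportClass NCLE
setClass("NCLE",
  representation(loop = "integer", gN = "numeric", gC = "numeric",
                 crossings = "data.frame", representative = "logical",
                 clusterId = "integer"))

setValidity("NCLE", function(object) {
  if (object@loop[1] >= object@loop[2]) return("loop must satisfy i < j")
  cr <- object@crossings
  if (nrow(cr) > 0 &&
      any(cr$residue >= object@loop[1] & cr$residue <= object@loop[2]))
    return("crossing residues must lie in a tail, not inside the loop")
  TRUE
})

#' EntangledRegionMask: per-residue entangled-region indicator
#'
#' @slot proteinId character.
#' @slot mask logical vector over residues 1..N.
#' @slot sourceLoops list of the representative NCLE loops used.
#' @exportClass EntangledRegionMask
setClass("EntangledRegionMask",
  representation(proteinId = "character", mask = "logical",
                 sourceLoops = "list"))

#' ContingencyResult: 2x2 association summary
#'
#' Counts a (exposed, outcome+), b (exposed, outcome-), c (unexposed,
#' outcome+), d (unexposed, outcome-) with the cross-product odds ratio,
#' Woolf (logit-scale) 95 percent confidence interval, and the two-sided
#' Fisher exact p-value.
#'
#' @slot a,b,c,d numeric non-negative counts.
#' @slot oddsRatio,ciLow,ciHigh,pValue numeric.
#' @slot undefined logical; TRUE when a zero margin makes the OR undefined.
#' @exportClass ContingencyResult
setClass("ContingencyResult",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 oddsRatio = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 pValue = "numeric", undefined = "logical"))

setValidity("ContingencyResult", function(object) {
  if (any(c(object@a, object@b, object@c, object@d) < 0))
    return("counts must be non-negative")
  if (!object@undefined &&
      (object@oddsRatio < object@ciLow || object@oddsRatio > object@ciHigh))
    return("CI must bracket the odds ratio")
  TRUE
})

#' LogisticFit: length-adjusted odds ratio from logistic regression
#'
#' Fit of logit P(outcome) = beta0 + beta1 * E + beta2 * L where E is the
#' binary exposure and L the standardized protein length. The adjusted odds
#' ratio is exp(beta1) with a Wald 95 percent CI.
#'
#' @slot beta0,beta1,beta2 numeric coefficients.
#' @slot adjustedOR,ciLow,ciHigh,pValue numeric.
#' @slot converged logical; FALSE flags separation/non-convergence.
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(beta0 = "numeric", beta1 = "numeric", beta2 = "numeric",
                 adjustedOR = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 pValue = "numeric", converged = "logical"))

#' GoModel: Calpha structure-based force field
#'
#' Harmonic bonds and angles, 1- and 3-fold cosine dihedrals with native
#' equilibrium values, 12-10 attractive wells on the native contact pairs and
#' purely repulsive r^-12 interactions elsewhere.
#'
#' @slot n integer bead count.
#' @slot bonds,angles,dihedrals,pairs numeric parameter matrices (1-based
#'   indices, native equilibrium values, force constants in kcal/mol units).
#' @slot repEps,repSigma numeric excluded-volume parameters.
#' @slot repMinSep integer minimum separation for the repulsive term.
#' @slot nativeCoords numeric n x 3 reference coordinates.
#' @exportClass GoModel
setClass("GoModel",
  representation(n = "integer", bonds = "matrix", angles = "matrix",
                 dihedrals = "matrix", pairs = "matrix", repEps = "numeric",
                 repSigma = "numeric", repMinSep = "integer",
                 nativeCoords = "matrix"))

setValidity("GoModel", function(object) {
  if (object@n < 5) return("chain must have at least 5 residues")
  if (nrow(object@bonds) != object@n - 1) return("need n-1 bonds")
  TRUE
})

#' QuenchProtocol: thermal-unfold / temperature-quench schedule
#'
#' @slot tUnfoldNs,tTrajNs numeric leg durations (ns).
#' @slot tempUnfold,tempQuench numeric temperatures (K).
#' @slot dtFs numeric time step (fs).
#' @slot frictionPs numeric Langevin friction (1/ps).
#' @slot nTraj integer number of independent trajectories.
#' @slot saveStride integer steps between saved frames.
#' @exportClass QuenchProtocol
setClass("QuenchProtocol",
  representation(tUnfoldNs = "numeric", tempUnfold = "numeric",
                 tempQuench = "numeric", dtFs = "numeric",
                 frictionPs = "numeric", nTraj = "integer",
                 tTrajNs = "numeric", saveStride = "integer"))

setValidity("QuenchProtocol", function(object) {
  v <- c(object@tUnfoldNs, object@tempUnfold, object@tempQuench, object@dtFs,
         object@frictionPs, object@nTraj, object@tTrajNs, object@saveStride)
  if (any(v <= 0)) return("all protocol parameters must be positive")
  TRUE
})

#' StateAssignment: per-frame microstate and macrostate labels
#'
#' @slot micro integer per-frame microstate (1..k).
#' @slot macro integer per-frame macrostate.
#' @slot nativeMacro integer id of the native macrostate (highest mean Q,
#'   lowest mean G).
#' @slot centers numeric k x 2 microstate centroids on the standardized
#'   (Q, G) plane.
#' @slot qg numeric matrix of the clustered (Q, G) values.
#' @exportClass StateAssignment
setClass("StateAssignment",
  representation(micro = "integer", macro = "integer",
                 nativeMacro = "integer", centers = "matrix", qg = "matrix"))

#' MisfoldingEstimate: misfolding probability over an analysis window
#'
#' P_mis = N_mis / (N_native + N_mis) * 100, where N_native counts frames in
#' the native macrostate and N_mis counts frames in non-native macrostates
#' with Q at or above the near-native floor.
#'
#' @slot nMis,nNative integer frame counts.
#' @slot pMis numeric percentage.
#' @exportClass MisfoldingEstimate
setClass("MisfoldingEstimate",
  representation(nMis = "integer", nNative = "integer", pMis = "numeric"))

setValidity("MisfoldingEstimate", function(object) {
  tot <- object@nMis + object@nNative
  if (tot > 0 && abs(object@pMis - 100 * object@nMis / tot) > 1e-9)
    return("pMis must equal nMis/(nNative+nMis)*100")
  TRUE
})
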