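#' Accessor generics
#'
#' Small accessor family for the package's S4 objects: \code{caCoords} returns
#' the Calpha coordinate matrix, \code{nResidues} the residue count,
#' \code{plddt} the per-residue confidence scores, \code{contacts} the contact
#' matrix, and \code{oddsRatio} the point estimate of an association result.
#'
#' @param object an S4 object from this package.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("caCoords", function(object) standardGeneric("caCoords"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("plddt", function(object) standardGeneric("plddt"))

#' @rdname accessors
#' @export
setGeneric("contacts", function(object) standardGeneric("contacts"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' @rdname accessors
#' @export
setMethod("caCoords", "ProteinStructure", function(object) object@caCoords)

#' @rdname accessors
#' @export
setMethod("nResidues", "ProteinStructure",
          function(object) nrow(object@caCoords))

#' @rdname accessors
#' @export
setMethod("plddt", "ProteinStructure", function(object) {
  if (length(object@plddt) == 0) NULL else object@plddt
})

#' @rdname accessors
#' @export
setMethod("contacts", "ContactMap", function(object) object@contacts)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "ContingencyResult", function(object) object@oddsRatio)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "LogisticFit", function(object) object@adjustedOR)

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure", object@id, "with", nResidues(object), "residues,",
      nrow(object@atoms), "heavy atoms")
  if (length(object@plddt) > 0)
    cat(sprintf(", mean pLDDT %.1f", mean(object@plddt)))
  cat("\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d contacts (cutoff %.1f A, |i-j| > %d)\n",
              nrow(object@contacts), object@cutoff, object@minSeqSep))
})

setMethod("show", "NCLE", function(object) {
  cat(sprintf("NCLE loop (%d, %d) gN=%.2f gC=%.2f, %d crossing(s)%s\n",
              object@loop[1], object@loop[2], object@gN, object@gC,
              nrow(object@crossings),
              if (isTRUE(object@representative)) " [representative]" else ""))
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("2x2 table  a=%d b=%d c=%d d=%d\n",
              object@a, object@b, object@c, object@d))
  if (object@undefined) {
    cat("odds ratio undefined (zero margin)\n")
  } else {
    cat(sprintf("OR = %.2f  (95%% CI [%.2f, %.2f]), Fisher p = %.3g\n",
                object@oddsRatio, object@ciLow, object@ciHigh, object@pValue))
  }
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf(
    "logistic fit: adjusted OR = %.2f (95%% CI [%.2f, %.2f]), p = %.3g%s\n",
    object@adjustedOR, object@ciLow, object@ciHigh, object@pValue,
    if (!object@converged) " [NOT CONVERGED]" else ""))
})

setMethod("show", "GoModel", function(object) {
  cat(sprintf(
    "GoModel: %d beads, %d native pairs, %d dihedrals, eps=%.2f kcal/mol\n",
    object@n, nrow(object@pairs), nrow(object@dihedrals),
    if (nrow(object@pairs)) object@pairs[1, 4] else NA_real_))
})

setMethod("show", "StateAssignment", function(object) {
  cat(sprintf(
    "StateAssignment: %d frames, %d microstates, %d macrostates (native = %d)\n",
    length(object@micro), nrow(object@centers),
    length(unique(object@macro)), object@nativeMacro))
})

setMethod("show", "MisfoldingEstimate", function(object) {
  cat(sprintf("P_mis = %.1f%%  (N_mis = %d, N_native = %d)\n",
              object@pMis, object@nMis, object@nNative))
})
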