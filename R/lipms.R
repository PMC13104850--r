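#' Read a LiP-MS peptide table
#'
#' Expected columns (TSV or CSV, header required): \code{protein},
#' \code{start}, \code{end} (1-based inclusive residue span), \code{kind}
#' ("tryptic" or "half_tryptic"), \code{pk_terminus} ("start", "end" or
#' "none"; the proteinase-K-generated end of a half-tryptic peptide),
#' \code{fold_change} and \code{adj_p}. The fold-change column may be stored
#' on the linear ratio scale or as log2; set \code{fcScale} accordingly —
#' significance thresholds are always applied on the linear |ratio| scale.
#'
#' @param path file path.
#' @param fcScale "linear" or "log2".
#' @return data.frame of validated peptide records with a linear
#'   \code{fold_change} column.
#' @export
readPeptideTable <- function(path, fcScale = c("linear", "log2")) {
  fcScale <- match.arg(fcScale)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("protein", "start", "end", "kind", "pk_terminus", "fold_change",
            "adj_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  validatePeptides(df, fcScale)
}

#' Validate (and rescale) a peptide record data.frame
#'
#' @param df data.frame in the \code{\link{readPeptideTable}} dialect.
#' @param fcScale "linear" or "log2".
#' @return the validated data.frame, fold changes on the linear scale.
#' @export
validatePeptides <- function(df, fcScale = c("linear", "log2")) {
  fcScale <- match.arg(fcScale)
  if (any(df$start > df$end)) stop("peptide spans must satisfy start <= end")
  if (!all(df$kind %in% c("tryptic", "half_tryptic")))
    stop("kind must be 'tryptic' or 'half_tryptic'")
  bad <- (df$kind == "tryptic") != (df$pk_terminus == "none")
  if (any(bad))
    stop("pk_terminus must be 'none' iff kind is 'tryptic' (",
         sum(bad), " offending rows)")
  if (fcScale == "log2") df$fold_change <- 2^df$fold_change
  df
}

#' Peptide-level significance call
#'
#' A peptide exhibits a significant age-associated abundance difference when
#' |fold change| > \code{fcThreshold} and adjusted p < \code{alpha}, both
#' strict.
#'
#' @param peptides peptide data.frame (linear fold changes).
#' @param fcThreshold fold-change threshold (default 5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return logical vector, one element per peptide.
#' @export
isSignificant <- function(peptides, fcThreshold = 5, alpha = 0.05) {
  if (any(is.na(peptides$adj_p))) stop("missing adjusted p-values")
  abs(peptides$fold_change) > fcThreshold & peptides$adj_p < alpha
}

#' Protein-level structural-change classification
#'
#' A protein exhibits an age-associated structural change iff at least one of
#' its peptides is significant. Proteins with zero observed peptides are
#' "not observed" (NA), which is distinct from FALSE.
#'
#' @param peptides peptide data.frame for one protein or many (grouped by the
#'   \code{protein} column).
#' @param fcThreshold,alpha thresholds passed to \code{\link{isSignificant}}.
#' @return named logical vector per protein id.
#' @export
classifyProteinChange <- function(peptides, fcThreshold = 5, alpha = 0.05) {
  if (nrow(peptides) == 0)
    return(setNames(logical(0), character(0)))
  sig <- isSignificant(peptides, fcThreshold, alpha)
  agg <- tapply(sig, peptides$protein, any)
  setNames(as.logical(agg), names(agg))[unique(peptides$protein)]
}

#' Map a significant peptide to its altered proteolytic cleavage site
#'
#' Half-tryptic peptides are assigned the residue at the proteinase-K
#' generated terminus; tryptic peptides use the central residue of the span,
#' floor((start + end)/2) for even-length spans. A +/-\code{buffer} residue
#' neighbourhood (clipped to the chain) absorbs positional uncertainty.
#'
#' @param peptide a single-row peptide data.frame.
#' @param proteinLength chain length N for clipping.
#' @param buffer sequence buffer (default 3).
#' @return list with \code{protein}, \code{residue}, \code{buffered} (integer
#'   vector), or NULL when the site falls outside 1..N (a warning is given).
#' @export
mapCleavageSite <- function(peptide, proteinLength, buffer = 3L) {
  stopifnot(nrow(peptide) == 1)
  if (peptide$kind == "half_tryptic") {
    if (peptide$pk_terminus == "none")
      stop("half-tryptic peptide lacks a proteinase-K terminus")
    site <- if (peptide$pk_terminus == "start") peptide$start else peptide$end
  } else {
    site <- floor((peptide$start + peptide$end) / 2)
  }
  if (site < 1 || site > proteinLength) {
    warning("cleavage site ", site, " outside chain 1..", proteinLength,
            "; peptide dropped")
    return(NULL)
  }
  list(protein = peptide$protein, residue = as.integer(site),
       buffered = seq(max(1L, site - buffer),
                      min(proteinLength, site + buffer)))
}

#' Per-residue proteolytic-alteration mask
#'
#' TRUE on the union of the buffered neighbourhoods of all altered cleavage
#' sites mapped from the protein's significant peptides.
#'
#' @param peptides peptide data.frame for one protein.
#' @param proteinLength chain length N.
#' @param buffer sequence buffer (default 3).
#' @param fcThreshold,alpha significance thresholds.
#' @return logical vector over residues 1..N.
#' @export
residueAlterationMask <- function(peptides, proteinLength, buffer = 3L,
                                  fcThreshold = 5, alpha = 0.05) {
  mask <- rep(FALSE, proteinLength)
  if (nrow(peptides) == 0) return(mask)
  sig <- isSignificant(peptides, fcThreshold, alpha)
  for (r in which(sig)) {
    site <- mapCleavageSite(peptides[r, , drop = FALSE], proteinLength,
                            buffer)
    if (!is.null(site)) mask[site$buffered] <- TRUE
  }
  mask
}
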