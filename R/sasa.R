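#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral Shrake-Rupley SASA with a 1.4 A probe. Atomic
#' models use per-element van der Waals radii; a bare Calpha trace falls back
#' to the Calpha-sphere approximation with a uniform 3.4 A residue radius
#' (one sphere per residue), which is the native code path for
#' coarse-grained frames. Outputs are labeled with the approximation used.
#'
#' @param conformation a \linkS4class{ProteinStructure}, or an n x 3 Calpha
#'   coordinate matrix (treated as the Calpha-sphere model).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param nPoints test points per sphere (default 256).
#' @param caRadius uniform Calpha-sphere radius (default 3.4).
#' @return numeric per-residue SASA (A^2) with attribute
#'   \code{model} ("atomic" or "ca_sphere").
#' @export
residueSasa <- function(conformation, probe = 1.4, nPoints = 256L,
                        caRadius = 3.4) {
  vdw <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
  if (is(conformation, "ProteinStructure") &&
      any(conformation@atoms$elety != "CA")) {
    a <- conformation@atoms
    xyz <- as.matrix(a[, c("x", "y", "z")])
    radii <- vdw[toupper(substr(a$element, 1, 1))]
    radii[is.na(radii)] <- 1.7
    areas <- cpp_sasa(xyz, radii, probe, as.integer(nPoints))
    out <- as.numeric(tapply(areas, a$resno, sum))
    attr(out, "model") <- "atomic"
  } else {
    ca <- if (is(conformation, "ProteinStructure"))
      caCoords(conformation) else as.matrix(conformation)
    if (anyDuplicated(round(ca, 6)))
      stop("overlapping identical atoms")
    out <- as.numeric(cpp_sasa(ca, rep(caRadius, nrow(ca)), probe,
                               as.integer(nPoints)))
    attr(out, "model") <- "ca_sphere"
  }
  out
}

#' Mean SASA over a sequence window around a site
#'
#' The consistency analysis compares, per cleavage site, the mean SASA of the
#' residues within \code{halfwidth} positions of the site (clipped to the
#' chain) between conformational ensembles.
#'
#' @param sasaMatrix conformations x residues SASA matrix (rows = ensemble
#'   members).
#' @param site residue index.
#' @param halfwidth window half-width (default 5).
#' @return numeric vector: per-conformation window mean (A^2).
#' @export
sasaWindow <- function(sasaMatrix, site, halfwidth = 5L) {
  n <- ncol(sasaMatrix)
  win <- seq(max(1L, site - halfwidth), min(n, site + halfwidth))
  rowMeans(sasaMatrix[, win, drop = FALSE])
}

#' Two-sided permutation test for a difference in ensemble means
#'
#' Tests the null that the two ensembles share a mean by permuting the pooled
#' labels: p = (1 + #{|mean difference| of a permutation >= observed}) /
#' (nPerm + 1). The +1 correction keeps p strictly positive. Seed-
#' deterministic.
#'
#' @param x,y numeric ensembles (each n >= 5).
#' @param nPerm permutations (default 1e5).
#' @param seed integer seed.
#' @return raw p-value.
#' @export
permutationTest <- function(x, y, nPerm = 1e5, seed = 1) {
  if (length(x) < 5 || length(y) < 5) stop("both ensembles need n >= 5")
  obs <- abs(mean(x) - mean(y))
  if (obs == 0) return(1)
  # sorting the pool makes the finite-sample p exactly symmetric in (x, y)
  pool <- sort(c(x, y))
  n1 <- length(x)
  exceed <- withSeed(seed, {
    cnt <- 0L
    for (b in seq_len(nPerm)) {
      idx <- sample.int(length(pool), n1)
      d <- abs(mean(pool[idx]) - mean(pool[-idx]))
      if (d >= obs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  (1 + exceed) / (nPerm + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, order-preserving (delegates to
#' \code{stats::p.adjust}).
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' LiP-MS consistency of clustered states
#'
#' For each non-native metastable state and each altered proteolytic site,
#' the window-mean SASA ensemble of the state is compared to the native
#' ensemble with the permutation test; all (state, site) p-values of one
#' protein form a single BH family. A state is consistent with the LiP-MS
#' evidence when at least one of its sites has adjusted p < \code{alpha}.
#' States with fewer than 5 conformations are skipped with a warning.
#'
#' @param stateEnsembles named list of conformations x residues SASA
#'   matrices, one per non-native state.
#' @param nativeEnsemble conformations x residues SASA matrix of the native
#'   state.
#' @param sites integer residue indices of the altered cleavage sites.
#' @param halfwidth window half-width (default 5).
#' @param nPerm permutations per test.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param seed integer seed.
#' @return data.frame with one row per (state, site): raw and adjusted p and
#'   the per-state \code{consistent} flag.
#' @export
stateConsistency <- function(stateEnsembles, nativeEnsemble, sites,
                             halfwidth = 5L, nPerm = 1e4, alpha = 0.05,
                             seed = 1) {
  rows <- list()
  k <- 0L
  for (s in names(stateEnsembles)) {
    ens <- stateEnsembles[[s]]
    if (nrow(ens) < 5) {
      warning("state ", s, " has fewer than 5 conformations; skipped")
      next
    }
    for (site in sites) {
      k <- k + 1L
      p <- permutationTest(sasaWindow(ens, site, halfwidth),
                           sasaWindow(nativeEnsemble, site, halfwidth),
                           nPerm = nPerm, seed = seed + k)
      rows[[k]] <- data.frame(state = s, site = site, p_raw = p,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(state = character(0), site = integer(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      consistent = logical(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p_raw)
  cons <- tapply(out$p_adj < alpha, out$state, any)
  out$consistent <- as.logical(cons[out$state])
  out
}
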