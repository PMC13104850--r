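#' Fraction of native contacts Q
#'
#' Q = (1/N_native) sum over native pairs of Theta(1.2 r_ij^0 - r_ij(t)):
#' a native contact counts as formed when the frame Calpha distance is at
#' most \code{factor} times its native distance, with boundary equality
#' counting as formed (Theta(0) = 1).
#'
#' @param frame n x 3 Calpha coordinates.
#' @param nativePairs matrix with columns i, j, r0 (native Calpha distance) —
#'   e.g. a \linkS4class{GoModel}'s \code{pairs} or
#'   \code{\link{nativePairsFromMap}} output.
#' @param factor distance tolerance factor (default 1.2).
#' @return Q in [0, 1].
#' @export
computeQ <- function(frame, nativePairs, factor = 1.2) {
  if (nrow(nativePairs) == 0) stop("empty native contact list")
  i <- nativePairs[, 1]; j <- nativePairs[, 2]; r0 <- nativePairs[, 3]
  d <- sqrt(rowSums((frame[i, , drop = FALSE] - frame[j, , drop = FALSE])^2))
  mean(d <= factor * r0 + 1e-12)
}

#' Native Calpha pair list from a contact map
#'
#' @param structure the native \linkS4class{ProteinStructure}.
#' @param contactMap a \linkS4class{ContactMap}.
#' @return matrix with columns i, j, r0 (native Calpha-Calpha distance).
#' @export
nativePairsFromMap <- function(structure, contactMap) {
  ca <- caCoords(structure)
  cc <- contacts(contactMap)
  i <- cc[, 1]; j <- cc[, 2]
  r0 <- sqrt(rowSums((ca[i, , drop = FALSE] - ca[j, , drop = FALSE])^2))
  cbind(i = i, j = j, r0 = r0)
}

#' Reference linking values for every native contact
#'
#' Precomputes the native gN/gC of each native-contact loop; the rounded
#' values are the topological reference that \code{\link{computeG}} compares
#' against.
#'
#' @param ca native n x 3 Calpha coordinates.
#' @param nativePairs matrix with columns i, j (r0 ignored).
#' @return list with \code{loops} (integer matrix) and \code{gN}, \code{gC}
#'   numeric vectors.
#' @export
referenceLinking <- function(ca, nativePairs) {
  loops <- matrix(as.integer(nativePairs[, 1:2]), ncol = 2)
  g <- cpp_gauss_link_batch(as.matrix(ca), loops)
  list(loops = loops, gN = g[, "gN"], gC = g[, "gC"], n = nrow(ca))
}

#' Fraction of native contacts with changed entanglement G
#'
#' For each native contact loop, the frame's gN and gC are recomputed and
#' rounded to the nearest integer; the contact exhibits a change in
#' entanglement when either rounded value differs from the rounded native
#' reference. G is the fraction of changed contacts over the full reference
#' contact set, whether or not the contact is formed in the frame. Rounding
#' makes the comparison robust to thermal fluctuation of the raw linking
#' values: an integer change in linking is the topological event.
#'
#' @param frame n x 3 Calpha coordinates.
#' @param reference output of \code{\link{referenceLinking}}.
#' @return G in [0, 1].
#' @export
computeG <- function(frame, reference) {
  if (nrow(frame) != reference$n)
    stop("frame chain length differs from the reference")
  g <- cpp_gauss_link_batch(as.matrix(frame), reference$loops)
  changed <- round(g[, "gN"]) != round(reference$gN) |
    round(g[, "gC"]) != round(reference$gC)
  mean(changed)
}

#' Per-frame (Q, G) metrics for a set of trajectories
#'
#' @param frames list of n x 3 frame matrices.
#' @param nativePairs native pair matrix (i, j, r0).
#' @param reference output of \code{\link{referenceLinking}}.
#' @return data.frame with columns \code{frame}, \code{Q}, \code{G}.
#' @export
frameMetrics <- function(frames, nativePairs, reference) {
  data.frame(
    frame = seq_along(frames),
    Q = vapply(frames, computeQ, numeric(1), nativePairs = nativePairs),
    G = vapply(frames, computeG, numeric(1), reference = reference))
}

# KMeans++ seeding (deterministic per RNG state), then Lloyd refinement.
kmeansPlusPlus <- function(x, k, iterMax = 100) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (c in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    idx <- sample.int(n, 1, prob = probs)
    centers[c + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[idx, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  # Lloyd refinement; its "did not converge" warning at iter.max is benign
  # for assignment purposes (centroids have long since stabilized)
  suppressWarnings(kmeans(x, centers = centers, iter.max = iterMax,
                          algorithm = "Lloyd"))
}

# PCCA+ (inner-simplex variant): spectral lumping of a row-stochastic
# transition matrix into m metastable sets via its top m right eigenvectors.
pccaPlus <- function(Tmat, m) {
  k <- nrow(Tmat)
  if (m >= k) return(seq_len(k))
  # stationary distribution for the symmetrizing similarity transform
  ev <- eigen(t(Tmat))
  pi_ <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  pi_ <- pi_ / sum(pi_)
  Ds <- sqrt(pi_ + 1e-12)
  S <- diag(Ds) %*% Tmat %*% diag(1 / Ds)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  X <- diag(1 / Ds) %*% es$vectors[, seq_len(m), drop = FALSE]
  # normalize the trivial eigenvector to a constant
  X[, 1] <- 1
  # inner simplex: pick m rows as vertices
  verts <- integer(m)
  d <- rowSums(X^2)
  verts[1] <- which.max(d)
  Y <- X
  for (q in seq_len(m - 1)) {
    v <- Y[verts[q], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    proj <- as.numeric(Y %*% v)
    Y <- Y - outer(proj, v)
    verts[q + 1] <- which.max(rowSums(Y^2))
  }
  A <- tryCatch(solve(X[verts, , drop = FALSE]),
                error = function(e) MASS_ginv(X[verts, , drop = FALSE]))
  chi <- X %*% A
  apply(chi, 1, which.max)
}

# Moore-Penrose pseudoinverse fallback for near-singular vertex matrices.
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Cluster (Q, G) frames into microstates and macrostates
#'
#' Frames are standardized on (Q, G) and assigned to \code{kMicro}
#' microstates by KMeans++ under a fixed seed. A microstate
#' transition-count matrix at the given lag (counted within each trajectory,
#' regularized with a small pseudocount and row-normalized) is lumped into
#' macrostates with the PCCA+ algorithm. The macrostate count is taken from
#' \code{nMacro}, or chosen by the largest spectral gap of the transition
#' matrix when "auto". The native macrostate is the one with the highest
#' mean Q - G among its frames.
#'
#' @param qg matrix/data.frame with columns Q and G, frames in time order.
#' @param trajId integer vector separating independent trajectories
#'   (transitions are not counted across boundaries); a single trajectory by
#'   default.
#' @param kMicro number of microstates (default 100; reduced with a warning
#'   when there are fewer frames).
#' @param lag transition lag in saved frames (default 10).
#' @param nMacro macrostate count, or "auto".
#' @param seed integer seed for the KMeans++ initialization.
#' @return A \linkS4class{StateAssignment}.
#' @export
clusterStates <- function(qg, trajId = NULL, kMicro = 100L, lag = 10L,
                          nMacro = "auto", seed = 1) {
  qg <- as.matrix(qg[, c(1, 2)])
  colnames(qg) <- c("Q", "G")
  nf <- nrow(qg)
  if (is.null(trajId)) trajId <- rep(1L, nf)
  if (nf < kMicro) {
    warning("fewer frames (", nf, ") than microstates (", kMicro,
            "); reducing kMicro")
    kMicro <- max(2L, nf %/% 2L)
  }
  mu <- colMeans(qg)
  sdv <- pmax(apply(qg, 2, sd), 1e-9)
  z <- sweep(sweep(qg, 2, mu), 2, sdv, "/")
  km <- withSeed(seed, kmeansPlusPlus(z, kMicro))
  micro <- km$cluster
  # lagged transition counts within trajectories
  k <- kMicro
  C <- matrix(1e-8, k, k)
  for (tr in unique(trajId)) {
    idx <- which(trajId == tr)
    if (length(idx) > lag) {
      from <- micro[idx[seq_len(length(idx) - lag)]]
      to <- micro[idx[-seq_len(lag)]]
      for (q in seq_along(from)) C[from[q], to[q]] <- C[from[q], to[q]] + 1
    }
  }
  Tmat <- C / rowSums(C)
  if (identical(nMacro, "auto")) {
    lam <- sort(abs(Re(eigen(Tmat, only.values = TRUE)$values)),
                decreasing = TRUE)
    m <- min(10, k)
    gaps <- lam[seq_len(m - 1)] - lam[seq(2, m)]
    nMacro <- which.max(gaps)
  }
  nMacro <- as.integer(nMacro)
  microMacro <- if (nMacro <= 1) rep(1L, k) else pccaPlus(Tmat, nMacro)
  macro <- microMacro[micro]
  # native macrostate: highest mean Q, lowest mean G
  score <- vapply(sort(unique(macro)), function(s)
    mean(qg[macro == s, "Q"]) - mean(qg[macro == s, "G"]), numeric(1))
  nativeMacro <- sort(unique(macro))[which.max(score)]
  new("StateAssignment", micro = as.integer(micro),
      macro = as.integer(macro), nativeMacro = as.integer(nativeMacro),
      centers = km$centers, qg = qg)
}

#' Misfolding probability over an analysis window
#'
#' P_mis = N_mis / (N_native + N_mis) x 100, counted over the window frames:
#' frames in the native macrostate count toward N_native; frames in
#' non-native macrostates whose Q is at least \code{qFloor} count as
#' near-native misfolded. Frames below the floor in non-native states are
#' grossly unfolded and count toward neither.
#'
#' @param assignment a \linkS4class{StateAssignment}.
#' @param window integer frame indices of the analysis window (e.g. the
#'   final 200 ns); all frames by default.
#' @param qFloor near-native Q floor (default 0.6).
#' @return A \linkS4class{MisfoldingEstimate}.
#' @export
misfoldingProbability <- function(assignment, window = NULL, qFloor = 0.6) {
  nf <- length(assignment@macro)
  if (is.null(window)) window <- seq_len(nf)
  if (length(window) == 0) stop("empty analysis window")
  mac <- assignment@macro[window]
  q <- assignment@qg[window, "Q"]
  nNative <- sum(mac == assignment@nativeMacro)
  nMis <- sum(mac != assignment@nativeMacro & q >= qFloor)
  tot <- nNative + nMis
  new("MisfoldingEstimate", nMis = as.integer(nMis),
      nNative = as.integer(nNative),
      pMis = if (tot == 0) NaN else 100 * nMis / tot)
}

#' Write per-frame metrics as TSV
#'
#' Columns frame, Q, G, micro, macro.
#'
#' @param metrics data.frame from \code{\link{frameMetrics}}.
#' @param assignment optional \linkS4class{StateAssignment} supplying state
#'   labels.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFrameMetricsTsv <- function(metrics, path, assignment = NULL) {
  if (!is.null(assignment)) {
    metrics$micro <- assignment@micro
    metrics$macro <- assignment@macro
  }
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
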