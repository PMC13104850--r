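#' @name synth
#' @title Synthetic-data generators with planted ground truth
#' @description Every pipeline stage has a generator that emulates the
#'   statistical structure of its real input and emits the planted truth
#'   alongside the data, so each stage can be round-trip tested (generate,
#'   analyze, recover the truth) without downloads. All generators are
#'   deterministic per seed.
NULL

# resample a polyline at fixed arclength spacing
resamplePolyline <- function(waypoints, spacing = 3.8) {
  seg <- diff(waypoints)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  svals <- seq(0, total, by = spacing)
  t(vapply(svals, function(s) {
    k <- max(which(cum <= s + 1e-9))
    if (k >= nrow(waypoints)) return(waypoints[nrow(waypoints), ])
    f <- (s - cum[k]) / len[k]
    waypoints[k, ] + f * seg[k, ]
  }, numeric(3)))
}

#' Loop-plus-tail curve with a planted linking number
#'
#' A circular loop of \code{nLoop} residues in the xy-plane (3.8 A spacing)
#' whose C-terminal tail either threads the loop perpendicularly
#' (\code{turns} passes of the same sense, linking number chirality x turns)
#' or stays in the loop plane outside the circle (linking 0). The first five
#' tail residues after the loop and the last five chain residues are routed
#' away from the loop plane so that the piercing falls inside the summation
#' window of the linking integrals. Gaussian positional noise is added and
#' the geometry regenerated (up to \code{retries}) if it self-intersects.
#'
#' @param nLoop loop residue count (>= 12).
#' @param threaded logical.
#' @param turns number of same-sense passes (1 or 2).
#' @param chirality +1 or -1.
#' @param noiseSd Gaussian jitter SD, Angstrom.
#' @param seed integer seed.
#' @param retries regeneration attempts on self-intersection.
#' @return list: \code{structure} (\linkS4class{ProteinStructure}),
#'   \code{loop} = c(i, j) residue indices of the loop, \code{truth} with the
#'   planted linking number.
#' @export
genLoopCurve <- function(nLoop = 24, threaded = TRUE, turns = 1,
                         chirality = 1, noiseSd = 0, seed = 1,
                         retries = 20) {
  stopifnot(nLoop >= 12, turns %in% c(1, 2), chirality %in% c(-1, 1))
  # distribute the loop points so the unclosed chord (the gap between the
  # first and last residue, bridged only by the closing contact) is ~2 A,
  # keeping the discretized loop nearly closed while residues stay 3.8 apart
  R <- (3.8 * (nLoop - 1) + 2.0) / (2 * pi)
  th <- seq(0, 2 * pi - 2.0 / R, length.out = nLoop)
  loopPts <- cbind(R * cos(th), R * sin(th), 0)
  exitPt <- loopPts[nLoop, ]
  H <- 4 * R  # vertical half-extent of each pass, large vs the loop radius
  if (threaded) {
    wp <- rbind(exitPt,
                c(R + 30, -6, 0),
                c(R + 30, 0, -H),
                c(0, 0, -H),
                c(0, 0, H))
    if (turns == 2)
      wp <- rbind(wp,
                  c(0, 12, H),
                  c(R + 30, 12, H - 5),
                  c(R + 30, 12, -H - 5),
                  c(6, 6, -H - 5),
                  c(6, 6, H))
    wp <- rbind(wp, wp[nrow(wp), ] + c(0, 0, 22))  # terminal pad (excluded)
  } else {
    wp <- rbind(exitPt, c(R + 6, -4, 0), c(R + 30, -4, 0),
                c(R + 50, -4, 0))
  }
  tailPts <- resamplePolyline(wp, 3.8)[-1, , drop = FALSE]
  base <- rbind(loopPts, tailPts)
  L <- if (threaded) chirality * turns else 0
  if (chirality < 0) base[, 3] <- -base[, 3]
  ca <- withSeed(seed, {
    for (att in seq_len(retries)) {
      cand <- base + matrix(rnorm(length(base), 0, noiseSd), ncol = 3)
      d <- as.matrix(dist(cand))
      d[abs(row(d) - col(d)) <= 1] <- Inf
      d[1, nrow(d)] <- d[nrow(d), 1] <- Inf  # contact-closing gap is tight
      if (min(d) > 1.5) break
      if (att == retries) stop("geometry self-intersects; reduce noiseSd")
    }
    cand
  })
  list(structure = structureFromCa(ca, sprintf("loop_curve_s%d", seed)),
       loop = c(1L, nLoop),
       truth = list(linking = L, threaded = threaded))
}

# ideal alpha-helix Calpha trace: rise 1.5 A, radius 2.3 A, 100 deg/residue
helixTrace <- function(n, origin = c(0, 0, 0), dirZ = 1, phase = 0) {
  k <- seq_len(n) - 1
  cbind(origin[1] + 2.3 * cos(phase + k * 100 * pi / 180),
        origin[2] + 2.3 * sin(phase + k * 100 * pi / 180),
        origin[3] + dirZ * 1.5 * k)
}

#' Mini-protein fixtures
#'
#' \code{helix_hairpin}: a 40-residue antiparallel two-helix bundle with no
#' entanglement — the folding fixture for the Go-model protocol.
#' \code{entangled_hairpin}: a 52-residue chain with a contact-closed
#' 20-residue loop threaded by the C-terminal tail; the planted loop-closing
#' contact and crossing residue are returned and the construction guarantees
#' |g| >= 0.6.
#'
#' @param motif "helix_hairpin" or "entangled_hairpin".
#' @param seed integer seed (adds 0.05 A deterministic jitter so seeds
#'   differ).
#' @return list: \code{structure}, \code{truth} (for the entangled variant:
#'   \code{loop}, \code{crossing}).
#' @export
genMiniProtein <- function(motif = c("helix_hairpin", "entangled_hairpin"),
                           seed = 1) {
  motif <- match.arg(motif)
  if (motif == "helix_hairpin") {
    h1 <- helixTrace(19, c(0, 0, 0), dirZ = 1)
    h2 <- helixTrace(19, c(8.5, 0, 26.5), dirZ = -1, phase = pi)
    turn <- resamplePolyline(rbind(h1[19, ], c(4.25, 3.5, 31.0),
                                   h2[1, ]), 3.8)
    turn <- turn[-c(1, nrow(turn)), , drop = FALSE]
    ca <- rbind(h1, turn, h2)
    truth <- list(entangled = FALSE)
  } else {
    nLoop <- 16
    R <- nLoop * 3.8 / (2 * pi)  # ~9.7 A
    # loop on a near-closed circle (closing chord ~3.8 A)
    th <- 2 * pi * (seq_len(nLoop) - 1) / nLoop
    loopPts <- cbind(R * cos(th), R * sin(th), 0)
    lead <- resamplePolyline(rbind(c(R + 22, 0, 6), c(R + 4, 0, 4),
                                   loopPts[1, ]), 3.8)
    lead <- lead[seq_len(4), , drop = FALSE]
    wp <- rbind(loopPts[nLoop, ],
                c(R + 20, -6, 0), c(R + 20, 0, -28), c(0, 0, -28),
                c(0, 0, 28), c(0, 0, 40))
    tailPts <- resamplePolyline(wp, 3.8)[-1, , drop = FALSE]
    ca <- rbind(lead, loopPts, tailPts)
    iLoop <- nrow(lead) + 1L
    jLoop <- nrow(lead) + nLoop
    # crossing: tail residue nearest the loop plane on the piercing segment
    tailIdx <- (jLoop + 1):nrow(ca)
    up <- tailIdx[ca[tailIdx, 3] > -10 & ca[tailIdx, 3] < 10 &
                    abs(ca[tailIdx, 1]) < 4 & abs(ca[tailIdx, 2]) < 4]
    crossing <- up[which.min(abs(ca[up, 3]))]
    truth <- list(entangled = TRUE, loop = c(iLoop, jLoop),
                  crossing = crossing)
  }
  ca <- withSeed(seed, ca + matrix(rnorm(length(ca), 0, 0.05), ncol = 3))
  list(structure = structureFromCa(ca, sprintf("%s_s%d", motif, seed)),
       truth = truth)
}

#' Synthetic LiP-MS peptide table with planted odds ratios
#'
#' Emulates the structure of the proteome analysis: a binary exposure (NCLE
#' presence), a binary outcome (age-associated structural change) and a
#' length confounder. Two modes share one interface. In \emph{marginal} mode
#' (default), exposure prevalence and per-group outcome prevalences are
#' planted directly (defaults mirror the observed scale: 74.7 percent of
#' proteins entangled, 21.8 vs 12.3 percent changed). In \emph{logistic}
#' mode (\code{beta} supplied), the outcome is drawn from
#' logit p = b0 + b1 E + b2 L with L the standardized log-normal length;
#' \code{confounded = TRUE} additionally makes length drive the exposure, so
#' the crude OR is biased while the adjusted OR recovers exp(b1).
#'
#' Changed proteins receive 1-3 significant peptides (|fold change| > 5,
#' adjusted p < 0.05) and every protein receives 3-8 insignificant ones;
#' kinds and proteinase-K termini are assigned at random.
#'
#' @param nProteins number of proteins.
#' @param prevalenceExposed,prevalenceUnexposed outcome prevalences
#'   (marginal mode).
#' @param fracEntangled exposure prevalence (marginal mode).
#' @param beta optional c(b0, b1, b2) for logistic mode.
#' @param confounded logical; length drives exposure (logistic mode).
#' @param meanLength,sdLog length distribution (log-normal).
#' @param emitPeptides set FALSE to return only the protein table (faster
#'   for statistical replication studies that do not touch peptides).
#' @param seed integer seed.
#' @return list: \code{proteins} (protein, entangled, length, changed),
#'   \code{peptides} (the \code{\link{readPeptideTable}} dialect),
#'   \code{truth} (planted ORs / coefficients).
#' @export
genPeptideTable <- function(nProteins = 2000,
                            prevalenceExposed = 0.218,
                            prevalenceUnexposed = 0.123,
                            fracEntangled = 0.747,
                            beta = NULL, confounded = FALSE,
                            meanLength = 400, sdLog = 0.45,
                            emitPeptides = TRUE, seed = 1) {
  stopifnot(prevalenceExposed > 0, prevalenceExposed < 1,
            prevalenceUnexposed > 0, prevalenceUnexposed < 1)
  withSeed(seed, {
    len <- pmax(60L, as.integer(round(
      exp(rnorm(nProteins, log(meanLength), sdLog)))))
    L <- (len - mean(len)) / sd(len)
    if (is.null(beta)) {
      E <- rbinom(nProteins, 1, fracEntangled) == 1
      p <- ifelse(E, prevalenceExposed, prevalenceUnexposed)
      truth <- list(
        proteinOR = (prevalenceExposed / (1 - prevalenceExposed)) /
          (prevalenceUnexposed / (1 - prevalenceUnexposed)))
    } else {
      stopifnot(length(beta) == 3)
      pe <- if (confounded) stats::plogis(0.5 + 1.5 * L) else
        rep(fracEntangled, nProteins)
      E <- rbinom(nProteins, 1, pe) == 1
      p <- stats::plogis(beta[1] + beta[2] * E + beta[3] * L)
      truth <- list(beta = beta, confounded = confounded)
    }
    changed <- rbinom(nProteins, 1, p) == 1
    ids <- sprintf("P%05d", seq_len(nProteins))
    proteins <- data.frame(protein = ids, entangled = E, length = len,
                           changed = changed, stringsAsFactors = FALSE)
    if (!emitPeptides)
      return(list(proteins = proteins, peptides = NULL, truth = truth))
    nSig <- ifelse(changed, sample(1:3, nProteins, replace = TRUE), 0L)
    nBg <- sample(3:8, nProteins, replace = TRUE)
    M <- sum(nSig) + sum(nBg)
    protein <- rep(ids, nSig + nBg)
    lenRep <- rep(len, nSig + nBg)
    sig <- unlist(mapply(function(s, b) rep(c(TRUE, FALSE), c(s, b)),
                         nSig, nBg, SIMPLIFY = FALSE))
    start <- 1L + as.integer(floor(runif(M) * pmax(1L, lenRep - 20L)))
    end <- pmin(lenRep, start + sample(6:17, M, replace = TRUE))
    kind <- sample(c("tryptic", "half_tryptic"), M, replace = TRUE)
    pk <- ifelse(kind == "half_tryptic",
                 sample(c("start", "end"), M, replace = TRUE), "none")
    sgn <- sample(c(-1, 1), M, replace = TRUE)
    fc <- ifelse(sig, sgn * runif(M, 5.5, 30), sgn * runif(M, 0.2, 4.5))
    adjp <- ifelse(sig, runif(M, 1e-6, 0.049), runif(M, 0.06, 1))
    peptides <- data.frame(protein = protein, start = start, end = end,
                           kind = kind, pk_terminus = pk, fold_change = fc,
                           adj_p = adjp, stringsAsFactors = FALSE)
    list(proteins = proteins, peptides = peptides, truth = truth)
  })
}

#' Synthetic (Q, G) series with planted state structure
#'
#' A Markov-switching Gaussian mixture on the (Q, G) plane: the chain sticks
#' in its current state with probability 1 - 1/\code{dwell} and otherwise
#' redraws a state from \code{populations} (whose stationary distribution is
#' exactly \code{populations}). Emissions are Gaussian around the state
#' means, clipped to [0, 1]^2.
#'
#' @param stateMeans list (or 2-column matrix) of (Q, G) state means.
#' @param populations state probabilities summing to 1.
#' @param nFrames series length.
#' @param noiseSd emission SD (default 0.03).
#' @param dwell mean dwell time in frames (default 20).
#' @param seed integer seed.
#' @return list: \code{qg} (nFrames x 2), \code{labels} (planted states),
#'   \code{truth} (populations).
#' @export
genQgSeries <- function(stateMeans, populations, nFrames = 5000,
                        noiseSd = 0.03, dwell = 20, seed = 1) {
  if (is.list(stateMeans)) stateMeans <- do.call(rbind, stateMeans)
  stopifnot(abs(sum(populations) - 1) < 1e-9,
            nrow(stateMeans) == length(populations))
  k <- length(populations)
  if (k > 1) {
    dmin <- min(dist(stateMeans))
    if (dmin < 2 * noiseSd)
      warning("state means closer than twice the noise SD; clusters overlap")
  }
  withSeed(seed, {
    lab <- integer(nFrames)
    lab[1] <- sample.int(k, 1, prob = populations)
    stay <- 1 - 1 / dwell
    for (t in seq(2, length.out = nFrames - 1))
      lab[t] <- if (runif(1) < stay) lab[t - 1] else
        sample.int(k, 1, prob = populations)
    qg <- stateMeans[lab, , drop = FALSE] +
      matrix(rnorm(2 * nFrames, 0, noiseSd), ncol = 2)
    qg[] <- pmin(1, pmax(0, qg))
    colnames(qg) <- c("Q", "G")
    list(qg = qg, labels = lab, truth = list(populations = populations))
  })
}

#' Paired SASA ensembles with planted window-mean shifts
#'
#' Residue-level SASA matrices for a native and a misfolded ensemble drawn
#' iid Gaussian per residue (mean 60 A^2, SD 8 A^2); at the residues within
#' +/-5 of each shifted site, the misfolded ensemble's mean is raised by
#' \code{shiftMagnitude} SDs. Sites are spaced so their windows do not
#' overlap.
#'
#' @param nNative,nMis ensemble sizes.
#' @param nSites number of candidate cleavage sites.
#' @param shiftSites indices (into the site list) that actually shift.
#' @param shiftMagnitude shift in units of the per-residue SD.
#' @param nRes chain length (default accommodates the sites).
#' @param seed integer seed.
#' @return list: \code{native}, \code{mis} (matrices conformations x
#'   residues), \code{sites} (residue indices), \code{truth}.
#' @export
genSasaEnsembles <- function(nNative = 100, nMis = 100, nSites = 5,
                             shiftSites = integer(0), shiftMagnitude = 1,
                             nRes = NULL, seed = 1) {
  stopifnot(all(shiftSites %in% seq_len(nSites)))
  if (is.null(nRes)) nRes <- nSites * 15 + 10
  sites <- 10 + 15 * (seq_len(nSites) - 1)
  withSeed(seed, {
    native <- matrix(rnorm(nNative * nRes, 60, 8), nNative, nRes)
    mis <- matrix(rnorm(nMis * nRes, 60, 8), nMis, nRes)
    for (s in shiftSites) {
      win <- seq(max(1, sites[s] - 5), min(nRes, sites[s] + 5))
      mis[, win] <- mis[, win] + shiftMagnitude * 8
    }
    list(native = native, mis = mis, sites = sites,
         truth = list(shiftSites = shiftSites,
                      shiftMagnitude = shiftMagnitude))
  })
}

#' Write generator ground truth as sidecar JSON
#'
#' Truth lives beside the data, never inside it, so analysis code cannot see
#' it.
#'
#' @param truth the \code{truth} element of a generator result.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
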