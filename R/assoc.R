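#' 2x2 contingency analysis with Woolf CI and Fisher test
#'
#' Builds the 2x2 table from binary exposure/outcome vectors, computes the
#' cross-product odds ratio (a d)/(b c), the Woolf logit-scale confidence
#' interval exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)), and the two-sided
#' Fisher exact p-value. A zero cell leaves the OR undefined and flags the
#' result; no continuity correction is applied unless \code{haldane = TRUE}.
#'
#' @param exposure,outcome equal-length logical vectors without missing
#'   values.
#' @param conf confidence level (default 0.95).
#' @param haldane add 0.5 to every cell when a zero is present.
#' @return A \linkS4class{ContingencyResult}.
#' @seealso \code{\link{contingencyFromCounts}} for printed tables.
#' @export
contingency <- function(exposure, outcome, conf = 0.95, haldane = FALSE) {
  stopifnot(length(exposure) == length(outcome),
            !anyNA(exposure), !anyNA(outcome))
  a <- sum(exposure & outcome)
  b <- sum(exposure & !outcome)
  c <- sum(!exposure & outcome)
  d <- sum(!exposure & !outcome)
  contingencyFromCounts(a, b, c, d, conf = conf, haldane = haldane)
}

#' @rdname contingency
#' @param a,b,c,d counts: exposed/outcome+, exposed/outcome-,
#'   unexposed/outcome+, unexposed/outcome-.
#' @export
contingencyFromCounts <- function(a, b, c, d, conf = 0.95, haldane = FALSE) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  undefined <- any(counts == 0)
  p <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
  if (undefined && haldane) {
    counts <- counts + 0.5
    undefined <- FALSE
  }
  if (undefined) {
    or <- ciL <- ciH <- NA_real_
  } else {
    or <- counts[1] * counts[4] / (counts[2] * counts[3])
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- sqrt(sum(1 / counts))
    ciL <- exp(log(or) - z * se)
    ciH <- exp(log(or) + z * se)
  }
  new("ContingencyResult", a = a, b = b, c = c, d = d, oddsRatio = or,
      ciLow = ciL, ciHigh = ciH, pValue = p, undefined = undefined)
}

#' Length-adjusted odds ratio by logistic regression
#'
#' Fits logit P(outcome) = beta0 + beta1 E + beta2 L by maximum likelihood,
#' where E is the binary exposure (e.g. NCLE presence) and L the protein
#' length standardized to zero mean and unit SD over the dataset. Longer
#' proteins are both more likely to contain entanglements and more likely to
#' have altered peptides mapped, so length is the confounder controlled here.
#' The adjusted OR is exp(beta1) with a Wald confidence interval.
#'
#' @param outcome,exposure logical vectors.
#' @param length integer/numeric protein lengths.
#' @param conf confidence level (default 0.95).
#' @return A \linkS4class{LogisticFit}; \code{converged = FALSE} flags
#'   separation or other non-convergence.
#' @export
adjustedOR <- function(outcome, exposure, length, conf = 0.95) {
  n <- base::length(outcome)
  stopifnot(n == base::length(exposure), n == base::length(length))
  if (n < 10) stop("need at least 10 observations")
  if (base::length(unique(exposure)) < 2)
    stop("exposure is constant; adjusted OR is undefined")
  L <- (length - mean(length)) / sd(length)
  fit <- suppressWarnings(
    glm(outcome ~ exposure + L, family = binomial()))
  sm <- summary(fit)$coefficients
  b <- coef(fit)
  se1 <- sm[2, 2]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  converged <- fit$converged && all(abs(b) < 15) && se1 < 1e3
  new("LogisticFit", beta0 = unname(b[1]), beta1 = unname(b[2]),
      beta2 = unname(b[3]), adjustedOR = exp(unname(b[2])),
      ciLow = exp(unname(b[2]) - z * se1), ciHigh = exp(unname(b[2]) + z * se1),
      pValue = sm[2, 4], converged = converged)
}

#' Percentile bootstrap confidence interval for the median
#'
#' @param values numeric vector, n >= 2.
#' @param iterations bootstrap resamples (default 1e6 as in the proteome
#'   analysis; reduce for quick checks).
#' @param seed integer seed; results are bit-reproducible per seed.
#' @param conf confidence level.
#' @return named numeric: \code{median}, \code{ciLow}, \code{ciHigh}.
#' @export
bootstrapMedianCI <- function(values, iterations = 1e6, seed = 1,
                              conf = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  meds <- withSeed(seed, {
    out <- numeric(iterations)
    chunk <- 10000L
    done <- 0L
    while (done < iterations) {
      k <- min(chunk, iterations - done)
      idx <- matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
      m <- matrix(values[idx], nrow = n)
      out[done + seq_len(k)] <- apply(m, 2, median)
      done <- done + k
    }
    out
  })
  qs <- quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(median = median(values), ciLow = qs[1], ciHigh = qs[2])
}

#' Brunner-Munzel rank test
#'
#' Nonparametric test of the stochastic-equality hypothesis
#' P(X < Y) + 0.5 P(X = Y) = 1/2 with the Brunner-Munzel t-approximation.
#' \code{alternative = "greater"} tests whether x tends to exceed y.
#'
#' @param x,y numeric samples (each n >= 5).
#' @param alternative "greater", "less" or "two.sided".
#' @return list with \code{statistic}, \code{df}, \code{pValue} and the
#'   stochastic-superiority estimate \code{pHat} = P(X < Y) + 0.5 P(X = Y).
#' @export
brunnerMunzel <- function(x, y, alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 5 || n2 < 5) stop("both samples must have n >= 5")
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  r1i <- rank(x); r2i <- rank(y)
  m1 <- mean(r1); m2 <- mean(r2)
  pHat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - r1i - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - r2i - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (n1 * v1 + n2 * v2 == 0) {
    if (length(unique(c(x, y))) == 1)
      stop("all observations tied; Brunner-Munzel statistic undefined")
    # complete separation: the statistic degenerates to +/- infinity
    stat <- sign(m2 - m1) * Inf
    df <- Inf
  } else {
    stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
    df <- (n1 * v1 + n2 * v2)^2 /
      ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  }
  p <- switch(alternative,
              greater = pt(stat, df),          # stat < 0 when x >> y
              less = pt(stat, df, lower.tail = FALSE),
              two.sided = 2 * pt(-abs(stat), df))
  list(statistic = stat, df = df, pValue = p, pHat = pHat)
}

#' Transcript-normalized abundance-increase calls
#'
#' Per protein: fold change = mean aged abundance / mean young abundance over
#' replicates. When the matching transcript changed at least two-fold
#' (|log2 FC| > 1) with Welch p < 0.01, the protein fold change is divided by
#' the transcript fold change (the transcript-derived normalization factor);
#' otherwise the factor is 1. A protein exhibits an age-associated abundance
#' increase when its normalized fold change exceeds 1 and the Welch t-test on
#' its abundances gives p < 0.01 (two-tailed, unequal variance).
#'
#' @param proteinTable data.frame: column \code{protein} plus young/aged
#'   replicate columns named \code{young_*} and \code{aged_*} (3 replicates
#'   per condition in the source data).
#' @param transcriptTable same dialect for transcripts (4 replicates per
#'   condition), or NULL to skip normalization.
#' @return data.frame with \code{protein}, \code{protein_fc},
#'   \code{transcript_factor}, \code{normalized_fc}, \code{p_value},
#'   \code{increased}.
#' @export
abundanceCalls <- function(proteinTable, transcriptTable = NULL) {
  ycols <- grep("^young", names(proteinTable), value = TRUE)
  acols <- grep("^aged", names(proteinTable), value = TRUE)
  stopifnot(length(ycols) >= 2, length(acols) >= 2)
  tf <- setNames(rep(1, nrow(proteinTable)), proteinTable$protein)
  if (!is.null(transcriptTable)) {
    tyc <- grep("^young", names(transcriptTable), value = TRUE)
    tac <- grep("^aged", names(transcriptTable), value = TRUE)
    for (r in seq_len(nrow(transcriptTable))) {
      ty <- as.numeric(transcriptTable[r, tyc])
      ta <- as.numeric(transcriptTable[r, tac])
      fc <- mean(ta) / mean(ty)
      pv <- t.test(ta, ty, var.equal = FALSE)$p.value
      if (abs(log2(fc)) > 1 && pv < 0.01) {
        id <- transcriptTable$protein[r]
        if (id %in% names(tf)) tf[id] <- fc
      }
    }
  }
  out <- lapply(seq_len(nrow(proteinTable)), function(r) {
    y <- as.numeric(proteinTable[r, ycols])
    a <- as.numeric(proteinTable[r, acols])
    if (mean(y) <= 0) stop("non-positive mean young abundance for protein ",
                           proteinTable$protein[r])
    fc <- mean(a) / mean(y)
    pv <- t.test(a, y, var.equal = FALSE)$p.value
    fac <- tf[[proteinTable$protein[r]]]
    nfc <- fc / fac
    data.frame(protein = proteinTable$protein[r], protein_fc = fc,
               transcript_factor = fac, normalized_fc = nfc, p_value = pv,
               increased = nfc > 1 & pv < 0.01, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
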