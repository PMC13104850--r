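test_that("null 2x2 table gives OR 1 and Fisher p 1, transpose symmetric", {
  r <- contingencyFromCounts(50, 50, 50, 50)
  expect_equal(oddsRatio(r), 1)
  expect_equal(r@pValue, 1)
  # transpose symmetry: swapping the roles of exposure and outcome
  r1 <- contingencyFromCounts(30, 10, 20, 40)
  r2 <- contingencyFromCounts(30, 20, 10, 40)
  expect_equal(oddsRatio(r1), oddsRatio(r2))
  # vector interface agrees with the count interface
  e <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 20, 40))
  o <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 20, 40))
  expect_equal(oddsRatio(contingency(e, o)), oddsRatio(r1))
})

test_that("zero cells flag the OR undefined unless Haldane is requested", {
  r <- contingencyFromCounts(0, 20, 10, 30)
  expect_true(r@undefined)
  expect_true(is.na(oddsRatio(r)))
  rh <- contingencyFromCounts(0, 20, 10, 30, haldane = TRUE)
  expect_false(rh@undefined)
  expect_gt(oddsRatio(rh), 0)
})

test_that("adjusted OR equals the crude OR when length is no confounder", {
  set.seed(21)
  n <- 5000
  E <- rbinom(n, 1, 0.5) == 1
  len <- rlnorm(n, log(300), 0.4)           # independent of E and outcome
  p <- ifelse(E, 0.3, 0.18)
  y <- rbinom(n, 1, p) == 1
  crude <- oddsRatio(contingency(E, y))
  adj <- adjustedOR(y, E, len)
  expect_true(adj@converged)
  expect_equal(oddsRatio(adj), crude, tolerance = 0.05)
  expect_error(adjustedOR(y, rep(TRUE, n), len), "constant")
})

test_that("separation is flagged as non-convergence", {
  set.seed(3)
  E <- rep(c(TRUE, FALSE), each = 30)
  y <- E                                   # perfectly separated by exposure
  len <- rnorm(60, 300, 50)
  fit <- adjustedOR(y, E, len)
  expect_false(fit@converged)
})

test_that("bootstrap median CI collapses for constants and brackets the
           median", {
  r <- bootstrapMedianCI(rep(3.5, 10), iterations = 200, seed = 1)
  expect_equal(unname(r), c(3.5, 3.5, 3.5))
  r2 <- bootstrapMedianCI(1:24, iterations = 2000, seed = 1)
  expect_lte(r2["ciLow"], 12.5)
  expect_gte(r2["ciHigh"], 12.5)
  # deterministic under a fixed seed
  expect_identical(r2, bootstrapMedianCI(1:24, iterations = 2000, seed = 1))
})

test_that("bootstrap median CI width matches the order-statistic
           approximation", {
  set.seed(7)
  x <- rnorm(24)
  r <- bootstrapMedianCI(x, iterations = 1e4, seed = 2)
  # large-sample SE of the median of n normals: 1.2533 sd / sqrt(n)
  se <- 1.2533 * sd(x) / sqrt(24)
  expect_equal(unname(r["ciHigh"] - r["ciLow"]), 2 * 1.96 * se,
               tolerance = 0.2)
})

test_that("Brunner-Munzel behaves at the null and under strong shifts", {
  set.seed(5)
  x <- rnorm(24)
  expect_equal(brunnerMunzel(x, x)$pValue, 0.5, tolerance = 1e-9)
  y <- rnorm(24) - 5
  expect_lt(brunnerMunzel(x, y, "greater")$pValue, 0.001)
  expect_gt(brunnerMunzel(y, x, "greater")$pValue, 0.999)
  expect_error(brunnerMunzel(rep(1, 10), rep(1, 10)), "tied")
  expect_error(brunnerMunzel(rnorm(4), rnorm(10)), "n >= 5")
})

test_that("Brunner-Munzel agrees with a permutation oracle on a small case", {
  set.seed(9)
  x <- rnorm(12, 0.8); y <- rnorm(12)
  bm <- brunnerMunzel(x, y, "greater")
  # oracle: permutation distribution of the same statistic
  pool <- c(x, y)
  stats <- replicate(4000, {
    idx <- sample(24, 12)
    brunnerMunzel(pool[idx], pool[-idx], "greater")$statistic
  })
  pPerm <- mean(stats <= bm$statistic)
  expect_lt(abs(bm$pValue - pPerm), 0.03)
})

test_that("abundance calls apply the transcript gate as specified", {
  prot <- data.frame(protein = c("A", "B"),
                     young_1 = c(10, 10), young_2 = c(11, 10.5),
                     young_3 = c(9, 9.5),
                     aged_1 = c(40, 41), aged_2 = c(39.5, 40),
                     aged_3 = c(40.5, 39))
  # transcript for A unchanged; for B a 4-fold increase with tiny p
  tx <- data.frame(protein = c("A", "B"),
                   young_1 = c(5, 5), young_2 = c(5.1, 5.05),
                   young_3 = c(4.9, 4.95), young_4 = c(5, 5.0),
                   aged_1 = c(5, 20), aged_2 = c(5.05, 20.2),
                   aged_3 = c(4.95, 19.8), aged_4 = c(5, 20.0))
  out <- abundanceCalls(prot, tx)
  expect_equal(out$transcript_factor[out$protein == "A"], 1)
  expect_equal(out$normalized_fc[out$protein == "A"],
               out$protein_fc[out$protein == "A"])
  expect_equal(out$normalized_fc[out$protein == "B"], 1, tolerance = 0.05)
  expect_true(out$increased[out$protein == "A"])
  expect_false(out$increased[out$protein == "B"])
  bad <- prot; bad$young_1 <- c(0, 0); bad$young_2 <- 0; bad$young_3 <- 0
  expect_error(abundanceCalls(bad, NULL), "non-positive")
})
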