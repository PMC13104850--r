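test_that("SASA of an isolated sphere equals the analytic area", {
  a <- residueSasa(matrix(c(0, 0, 0), 1, 3))
  expect_equal(as.numeric(a), 4 * pi * (3.4 + 1.4)^2, tolerance = 0.02)
})

test_that("a residue buried in a dense shell has near-zero SASA", {
  # golden-spiral shell of neighbours at 5 A around the origin
  n <- 60
  z <- 1 - 2 * (seq_len(n) - 0.5) / n
  r <- sqrt(1 - z^2)
  th <- pi * (3 - sqrt(5)) * seq_len(n)
  shell <- 5 * cbind(r * cos(th), r * sin(th), z)
  a <- residueSasa(rbind(c(0, 0, 0), shell))
  expect_lt(a[1], 0.02 * 4 * pi * 4.8^2)
})

test_that("two-sphere SASA matches the analytic spherical-cap formula", {
  d <- 4
  a <- residueSasa(rbind(c(0, 0, 0), c(d, 0, 0)))
  R <- 3.4 + 1.4
  # equal spheres: each loses a cap of height h = R - d/2
  h <- R - d / 2
  analytic <- 4 * pi * R^2 - 2 * pi * R * h
  expect_equal(as.numeric(a[1]), analytic, tolerance = 0.02)
  expect_equal(as.numeric(a[2]), analytic, tolerance = 0.02)
})

test_that("atomic-model SASA uses element radii and sums per residue", {
  pdb <- writeTinyPdb(tempfile(fileext = ".pdb"))
  s <- loadStructure(pdb)
  a <- residueSasa(s)
  expect_equal(attr(a, "model"), "atomic")
  expect_length(a, 4)
  expect_true(all(a > 0))
})

test_that("permutation p is 1 for identical ensembles and minimal under
           extreme separation", {
  set.seed(8)
  x <- rnorm(50)
  expect_equal(permutationTest(x, x, nPerm = 500, seed = 1), 1)
  sdp <- sd(c(x, x + 10 * sd(x)))
  y <- x + 10 * sdp
  expect_equal(permutationTest(x, y, nPerm = 2000, seed = 1), 1 / 2001)
  # exchange symmetry of the two-sided statistic
  a <- rnorm(30); b <- rnorm(30, 0.5)
  expect_equal(permutationTest(a, b, nPerm = 2000, seed = 3),
               permutationTest(b, a, nPerm = 2000, seed = 3))
  expect_error(permutationTest(rnorm(3), rnorm(10)), "n >= 5")
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  # hand computation for a non-degenerate vector
  p <- c(0.005, 0.04, 0.2, 0.5)
  expect_equal(bhAdjust(p), c(0.02, 0.08, 8 / 30, 0.5))
  # adjusted p dominate raw p and preserve their ordering
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p))
})

test_that("state consistency detects planted SASA shifts at the right
           sites", {
  fx <- genSasaEnsembles(nNative = 60, nMis = 60, nSites = 4,
                         shiftSites = 2, shiftMagnitude = 2, seed = 9)
  out <- stateConsistency(list(mis = fx$mis), fx$native, fx$sites,
                          nPerm = 2000, seed = 1)
  expect_true(all(out$consistent))
  expect_lt(out$p_adj[out$site == fx$sites[2]], 0.05)
  # identical ensembles: inconsistent
  fx0 <- genSasaEnsembles(nNative = 60, nMis = 60, nSites = 4,
                          shiftSites = integer(0), seed = 10)
  out0 <- stateConsistency(list(mis = fx0$native), fx0$native, fx0$sites,
                           nPerm = 500, seed = 1)
  expect_false(any(out0$consistent))
  # shift far from every site window
  fx2 <- genSasaEnsembles(nNative = 60, nMis = 60, nSites = 2,
                          shiftSites = integer(0), seed = 11, nRes = 60)
  mis <- fx2$mis; mis[, 55:60] <- mis[, 55:60] + 30
  out2 <- stateConsistency(list(mis = mis), fx2$native, fx2$sites,
                           nPerm = 2000, seed = 2)
  expect_false(any(out2$consistent))
  # undersized state ensembles are skipped with a warning
  expect_warning(
    empty <- stateConsistency(list(tiny = fx$mis[1:3, ]), fx$native,
                              fx$sites, nPerm = 100, seed = 1),
    "fewer than 5")
  expect_equal(nrow(empty), 0)
})
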