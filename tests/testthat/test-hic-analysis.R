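# In-silico Hi-C stack: contact maps, P(s), eigenvectors, correlations, FISH

twoFrameEnsemble <- function() {
  # beads 1 and 2 touch in frame 1 only
  m1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 5, 5))
  m2 <- rbind(c(0, 0, 0), c(4, 0, 0), c(5, 5, 5))
  chromEnsemble(beadRecords(3), list(m1, m2))
}

test_that("contact frequencies are frame fractions under the hard cutoff", {
  e1 <- chromEnsemble(beadRecords(3),
                      list(rbind(c(0, 0, 0), c(1, 0, 0), c(9, 9, 9))))
  m <- contactMatrix(contactMap(e1, rc = 1.5))
  expect_identical(m[1, 2], 1)
  expect_identical(m[1, 3], 0)
  expect_identical(diag(m), rep(1, 3))      # self-contacts: diagonal maximal
  m2 <- contactMatrix(contactMap(twoFrameEnsemble(), rc = 1.5))
  expect_identical(m2[1, 2], 0.5)
  expect_error(contactMap(twoFrameEnsemble(), rc = -1), "positive")
})

test_that("contact map matches the brute-force frame-by-pair oracle exactly", {
  e <- makeIdealChainEnsemble(12, 10, bondB = 1.2, seed = 3)
  got <- contactMatrix(contactMap(e, rc = 1.5))
  expect_identical(got, oracleContactMap(e@models, 1.5))
  expect_identical(got, t(got))
})

test_that("kernel mode averages the sigmoidal kernel over frames", {
  e <- twoFrameEnsemble()
  got <- contactMatrix(contactMap(e, rc = 1.78, mode = "kernel", mu = 3.22))
  want12 <- mean(c(contactKernel(1), contactKernel(4)))
  expect_equal(got[1, 2], want12, tolerance = 1e-12)
})

test_that("P(s) is the per-diagonal mean: flat for uniform, banded for nearest-neighbour maps", {
  u <- newContactMap(matrix(1, 5, 5))
  expect_identical(psCurve(u)$p, rep(1, 4))
  banded <- diag(5)
  banded[cbind(1:4, 2:5)] <- 1; banded[cbind(2:5, 1:4)] <- 1
  pb <- psCurve(newContactMap(banded))
  expect_identical(pb$p, c(1, 0, 0, 0))
  e <- makeIdealChainEnsemble(10, 8, seed = 11)
  map <- contactMap(e, rc = 1.5)
  expect_equal(psCurve(map)$p, oraclePs(contactMatrix(map)), tolerance = 1e-12)
  expect_identical(psCurve(map)$distance_bp, psCurve(map)$s * 50000)
})

test_that("the first Pearson eigenvector recovers planted blocks exactly when noiseless", {
  fx <- makeBlockContactMap(40, 4, pWithin = 0.9, pBetween = 0.1,
                            noise = 0, seed = 17)
  prof <- compartmentEigenvector(fx$map)
  expect_identical(signAgreement(eigenvector(prof), fx$labels), 1)
  expect_gt(prof@explainedShare, 0.3)
})

test_that("relabelling loci by a separation-preserving permutation permutes the eigenvector identically", {
  # the observed/expected step conditions on genomic separation, so the
  # equivariance that must hold is under separation-preserving relabellings:
  # chain reversal
  fx <- makeBlockContactMap(30, 3, noise = 0.1, seed = 19)
  m <- contactMatrix(fx$map)
  perm <- 30:1
  v1 <- eigenvector(compartmentEigenvector(fx$map))
  v2 <- eigenvector(compartmentEigenvector(newContactMap(m[perm, perm])))
  if (sign(v2[which.max(abs(v2))]) != sign(v1[perm][which.max(abs(v2))]))
    v2 <- -v2
  expect_equal(v2, v1[perm], tolerance = 1e-9)
})

test_that("degenerate maps are rejected with a named degeneracy", {
  expect_error(compartmentEigenvector(newContactMap(matrix(1, 6, 6))),
               "degenerate")
  expect_error(compartmentEigenvector(newContactMap(matrix(0, 6, 6))),
               "degenerate")
})

test_that("annotations orient the eigenvector sign so A-class loci are positive", {
  fx <- makeBlockContactMap(40, 4, noise = 0, seed = 29)
  ann <- ifelse(fx$labels == "A", "A1", "B2")
  prof <- compartmentEigenvector(fx$map, annotations = ann)
  expect_gt(mean(eigenvector(prof)[fx$labels == "A"]), 0)
  expect_match(prof@signConvention, "A-class")
})

test_that("eigenvector comparison aligns the arbitrary global sign and reports it", {
  fx <- makeBlockContactMap(30, 2, noise = 0.1, seed = 31)
  prof <- compartmentEigenvector(fx$map)
  self <- compareEigenvectors(prof, prof)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_identical(self$sign, 1)
  neg <- compareEigenvectors(prof, -eigenvector(prof))
  expect_equal(neg$r, 1, tolerance = 1e-12)
  expect_identical(neg$sign, -1)
  set.seed(33)
  x <- rnorm(25); y <- x + rnorm(25)
  expect_equal(compareEigenvectors(x, y)$r, oraclePearson(x, y),
               tolerance = 1e-12)
  expect_error(compareEigenvectors(x, rnorm(10)), "equal length")
  expect_error(compareEigenvectors(c(1, 2, NA, NA), c(1, 2, NA, NA)),
               "fewer than 3")
})

test_that("distance-stratified correlation: identity with itself, zero against shuffled diagonals", {
  fx <- makeBlockContactMap(30, 3, noise = 0.3, seed = 37)
  m <- contactMatrix(fx$map)
  self <- mapCorrelationByDistance(fx$map, fx$map)
  expect_true(all(abs(self$r[!is.na(self$r)] - 1) < 1e-12))
  # shuffle each diagonal independently -> correlation ~ 0
  set.seed(39)
  ms <- matrix(0, 30, 30)
  d <- row(m) - col(m)
  for (s in 1:28) {
    v <- m[d == s]
    sh <- sample(v)
    ms[d == s] <- sh; ms[d == -s] <- sh
  }
  diag(ms) <- diag(m)
  shuf <- mapCorrelationByDistance(m, ms, maxS = 15)
  expect_lt(mean(abs(shuf$r), na.rm = TRUE), 0.35)
  # symmetry in the arguments
  ab <- mapCorrelationByDistance(m, ms, maxS = 10)
  ba <- mapCorrelationByDistance(ms, m, maxS = 10)
  expect_equal(ab$r, ba$r, tolerance = 1e-12)
})

test_that("the 5x5 worked example matches hand-computed diagonal correlations", {
  mkSym <- function(d1, d2, d3, d4) {
    m <- diag(5) * 4
    m[cbind(1:4, 2:5)] <- d1; m[cbind(2:5, 1:4)] <- d1
    m[cbind(1:3, 3:5)] <- d2; m[cbind(3:5, 1:3)] <- d2
    m[cbind(1:2, 4:5)] <- d3; m[cbind(4:5, 1:2)] <- d3
    m[1, 5] <- d4; m[5, 1] <- d4
    m
  }
  A <- mkSym(c(2, 1, 3, 1), c(1, 2, 1), c(0, 1), 2)
  B <- mkSym(c(1, 1, 2, 0), c(2, 1, 1), c(1, 0), 3)
  res <- mapCorrelationByDistance(A, B)
  expect_equal(res$r, c(0.8528028654, -0.5, -1), tolerance = 1e-9)
  expect_equal(res$r,
               c(oraclePearson(c(2, 1, 3, 1), c(1, 1, 2, 0)),
                 oraclePearson(c(1, 2, 1), c(2, 1, 1)),
                 oraclePearson(c(0, 1), c(1, 0))),
               tolerance = 1e-12)
  # a constant diagonal has no defined correlation
  C <- mkSym(c(1, 1, 1, 1), c(2, 1, 1), c(1, 0), 3)
  expect_true(is.na(mapCorrelationByDistance(C, B)$r[1]))
  # unequal sizes: error unless truncation is requested
  expect_error(mapCorrelationByDistance(A, matrix(1, 7, 7)), "truncate")
  tr <- mapCorrelationByDistance(A, mkSym(c(1, 1, 2, 0), c(2, 1, 1), c(1, 0), 3)[1:5, 1:5],
                                 truncate = TRUE)
  expect_identical(nrow(tr), 3L)
})

test_that("FISH-style distance distributions: degenerate, two-point and averaged cases", {
  rigid <- chromEnsemble(beadRecords(3),
                         rep(list(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))), 4))
  d <- distanceDistribution(rigid, 1, 2)
  expect_identical(unique(d$samples), 3)
  expect_identical(d$mean, 3)
  two <- distanceDistribution(twoFrameEnsemble(), 1, 2)
  expect_setequal(two$samples, c(1, 4))
  expect_identical(mean(two$samples == 1), 0.5)
  expect_identical(two$mean, 2.5)
  expect_identical(two$median, 2.5)
  e <- makeIdealChainEnsemble(8, 25, seed = 41)
  dd <- distanceDistribution(e, 2, 7)
  brute <- mean(vapply(e@models, function(m) sqrt(sum((m[2, ] - m[7, ])^2)),
                       numeric(1)))
  expect_equal(dd$mean, brute, tolerance = 1e-12)
  expect_identical(sum(dd$histogram$count), 25L)
  expect_warning(z <- distanceDistribution(e, 3, 3), "identically zero")
  expect_identical(unique(z$samples), 0)
  expect_error(distanceDistribution(e, 1, 99), "range")
})
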