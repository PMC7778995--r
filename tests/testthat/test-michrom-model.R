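# Energy function: closed forms, oracles, invariances, MD-input export

test_that("contact kernel has the stated shape: bounds, midpoint, monotone decay", {
  expect_equal(contactKernel(1.78, 3.22, 1.78), 0.5)
  expect_gt(contactKernel(0), contactKernel(1.78))
  expect_gt(contactKernel(1.78), contactKernel(17.8))
  r <- seq(0, 10, by = 0.01)
  f <- contactKernel(r)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(contactKernel(-0.1), "non-negative")
})

test_that("FENE bond closed forms: zero at rest, divergence near r0, per-bond additivity", {
  p <- michromParameters()
  # two coincident beads: FENE contribution ln(1) = 0, core contribution eps
  pos0 <- rbind(c(0, 0, 0), c(1e-9, 0, 0))
  # at r ~ 0 the repulsive core dominates; isolate FENE with a sigma-sized bond
  cut <- 2^(1 / 6)
  posc <- rbind(c(0, 0, 0), c(cut, 0, 0))
  expect_equal(energyBonded(posc, p),
               -0.5 * 30 * 1.5^2 * log(1 - (cut / 1.5)^2), tolerance = 1e-12)
  # near-maximal extension diverges (logarithmically in 1 - r/r0)
  poss <- rbind(c(0, 0, 0), c(1.5 * (1 - 1e-6), 0, 0))
  expect_gt(energyBonded(poss, p), 400)
  poss2 <- rbind(c(0, 0, 0), c(1.5 * (1 - 1e-12), 0, 0))
  expect_gt(energyBonded(poss2, p), energyBonded(poss, p) + 400)
  # overstretch error names the bond
  expect_error(energyBonded(rbind(c(0, 0, 0), c(2, 0, 0)), p), "bond 1-2")
  # 5-bead chain equals the sum of 4 per-bond closed forms
  set.seed(71)
  pos <- matrix(cumsum(c(0, runif(4, 0.8, 1.2))), ncol = 1)
  pos <- cbind(pos, 0, 0)
  manual <- 0
  for (i in 1:4) {
    r <- pos[i + 1, 1] - pos[i, 1]
    manual <- manual + oracleFene(r, 30, 1.5) + oracleWca(r, 1, 1)
  }
  expect_equal(energyBonded(pos, p), manual, tolerance = 1e-12)
})

test_that("confinement is zero inside, quadratic outside, with inward gradient", {
  p <- michromParameters(confinementRadius = 4, confinementK = 7)
  expect_identical(energyConfinement(matrix(0, 3, 3), p), 0)
  pos <- rbind(c(5, 0, 0))          # distance R + 1
  expect_equal(energyConfinement(pos, p), 7 * 1^2, tolerance = 1e-12)
  # finite-difference gradient points radially inward
  sys <- chromosomeSystem(0L, parameters = p)
  f <- totalForces(sys, pos)
  expect_lt(f[1, 1], 0)
  h <- 1e-6
  num <- -(energyConfinement(rbind(c(5 + h, 0, 0)), p) -
             energyConfinement(rbind(c(5 - h, 0, 0)), p)) / (2 * h)
  expect_equal(f[1, 1], num, tolerance = 1e-5)
})

test_that("every pairwise term matches the O(n^2) brute-force oracle on random chains", {
  for (seed in c(81, 82, 83)) {
    set.seed(seed)
    n <- sample(10:30, 1)
    p <- michromParameters(confinementRadius = 4, dMax = 20L)
    pos <- initialConformation(n, 4, seed = seed)
    types <- sample(0:6, n, replace = TRUE)
    loops <- rbind(c(1L, n %/% 2L), c(2L, as.integer(n)))
    want <- oracleEnergies(pos, types, loops, p)
    got <- c(bonded = energyBonded(pos, p),
             confinement = energyConfinement(pos, p),
             ideal = energyIdealChromosome(pos, p),
             type = energyTypeToType(pos, types, p),
             loops = energyLoops(pos, loops, p))
    for (term in names(want))
      expect_equal(got[[term]], want[[term]], tolerance = 1e-10,
                   label = sprintf("%s (seed %d)", term, seed))
  }
})

test_that("ideal-chromosome term is translationally invariant in bead identity; type term is not", {
  set.seed(85)
  n <- 20
  p <- michromParameters(confinementRadius = 4, dMax = 15L)
  pos <- initialConformation(n, 4, seed = 85)
  types <- rep(c(0L, 2L), each = 10)
  permuted <- sample(types)
  # the ideal term never sees types at all
  expect_identical(energyIdealChromosome(pos, p), energyIdealChromosome(pos, p))
  e1 <- energyTypeToType(pos, types, p)
  e2 <- energyTypeToType(pos, permuted, p)
  expect_false(isTRUE(all.equal(e1, e2)))
  # equal-separation equal-distance pairs contribute equally to the ideal term
  d <- 5
  posA <- matrix(0, 12, 3); posA[, 1] <- seq(0, 11) * 1.0
  eA <- energyIdealChromosome(posA, p)
  posB <- posA; posB[, 2] <- 100  # rigid translation
  expect_equal(energyIdealChromosome(posB, p), eA, tolerance = 1e-12)
})

test_that("type couplings: attractive homotypic contact is negative, distant pairs vanish, unknown types error", {
  p <- michromParameters()
  pos3 <- rbind(c(0, 0, 0), c(500, 0, 0), c(1.1, 0, 0))
  # pair (1,3) is the only non-bonded pair within range; alpha(A1,A1) < 0
  e <- energyTypeToType(pos3, c(0L, 6L, 0L), p)
  expect_lt(e, 0)
  far <- rbind(c(0, 0, 0), c(500, 0, 0), c(1000, 0, 0))
  expect_equal(energyTypeToType(far, c(0L, 0L, 0L), p), 0, tolerance = 1e-9)
  expect_error(energyTypeToType(pos3, c(0L, 0L, 9L), p), "type")
})

test_that("loop term: empty list zero, coincident anchors chi*f(0), duplicates deduplicated with warning", {
  p <- michromParameters()
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0.001, 0.001, 0))
  expect_identical(energyLoops(pos, matrix(integer(), ncol = 2), p), 0)
  one <- energyLoops(pos, rbind(c(1L, 4L)), p)
  expect_equal(one, -1.5 * contactKernel(sqrt(2) * 0.001), tolerance = 1e-9)
  expect_warning(dup <- energyLoops(pos, rbind(c(1L, 4L), c(4L, 1L)), p),
                 "duplicate")
  expect_identical(dup, one)
})

test_that("total energy is the sum of its reportable terms and invariant under rigid isometries", {
  set.seed(91)
  n <- 10
  p <- michromParameters(confinementRadius = 4, dMax = 8L)
  sys <- chromosomeSystem(sample(0:5, n, replace = TRUE),
                          loops = rbind(c(1L, 9L)), parameters = p)
  pos <- initialConformation(n, 4, seed = 91)
  te <- totalEnergy(sys, pos)
  expect_equal(te$total, sum(te$terms), tolerance = 1e-12)
  want <- oracleEnergies(pos, beadTypes(sys), loops(sys), p)
  expect_equal(unname(te$terms), unname(want), tolerance = 1e-10)
  # single bead at the origin: all terms zero
  sys1 <- chromosomeSystem(0L, parameters = p)
  expect_identical(totalEnergy(sys1, matrix(0, 1, 3))$total, 0)
  # rotation about the confinement centre leaves every term unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  te_rot <- totalEnergy(sys, pos %*% t(R))
  expect_equal(te_rot$terms, te$terms, tolerance = 1e-9)
})

test_that("initial conformations are deterministic, confined, and bond-safe", {
  a <- initialConformation(150, 5, seed = 7)
  b <- initialConformation(150, 5, seed = 7)
  expect_identical(a, b)
  expect_true(all(sqrt(rowSums(a^2)) < 5))
  bonds <- sqrt(rowSums((a[-1, ] - a[-150, ])^2))
  expect_true(all(bonds < 1.5))
  expect_error(initialConformation(5000, 2, seed = 1), "cannot fit")
})

test_that("exported tables reproduce the in-package energy terms at off-grid points", {
  p <- michromParameters(confinementRadius = 4, dMax = 10L)
  sys <- makeBlockCopolymer(12, 6, seed = 1, parameters = p,
                            loops = rbind(c(2L, 9L)))
  pos <- initialConformation(12, 4, seed = 2)
  dir <- withr::local_tempdir()
  paths <- exportMdInputs(sys, pos, dir)
  expect_true(all(file.exists(paths)))
  interp <- function(path) {
    tb <- readXvg(path)
    function(r) spline(tb$r, tb$U, xout = r)$y
  }
  # confinement: closed form at R + 1 (a grid point) and off-grid points
  b1 <- interp(paths["table_b1"])
  expect_equal(b1(p@confinementRadius + 1), p@confinementK, tolerance = 1e-9)
  for (r in c(4.20013, 5.73917)) {
    want <- energyConfinement(rbind(c(r, 0, 0)), p)
    expect_equal(b1(r), want, tolerance = 1e-6 * max(1, abs(want)))
  }
  # bonded: per-bond energy off grid
  b0 <- interp(paths["table_b0"])
  for (r in c(0.95317, 1.20094)) {
    want <- energyBonded(rbind(c(0, 0, 0), c(r, 0, 0)), p)
    expect_equal(b0(r), want, tolerance = 1e-6 * abs(want))
  }
  # ideal basis: unit-gamma kernel
  b2 <- interp(paths["table_b2"])
  for (r in c(1.11113, 2.04447))
    expect_equal(b2(r), contactKernel(r, p@contactMu, p@contactRc),
                 tolerance = 1e-6)
  # type basis at reference coupling alpha = 1: steric core + kernel
  tb <- interp(paths["table"])
  for (r in c(1.0501, 1.89998)) {
    want <- oracleWca(r, 1, 1) + contactKernel(r, p@contactMu, p@contactRc)
    expect_equal(tb(r), want, tolerance = 1e-6 * max(1, abs(want)))
  }
  # loop table: chi * f
  tp <- interp(paths["tablep"])
  for (r in c(1.33339, 2.50001))
    expect_equal(tp(r), p@loopChi * contactKernel(r, p@contactMu, p@contactRc),
                 tolerance = 1e-6)
})

test_that("gro and top outputs carry the system: bead count, annotations, recoverable loops", {
  p <- michromParameters(confinementRadius = 4)
  sys <- makeBlockCopolymer(10, 5, seed = 1, parameters = p,
                            loops = rbind(c(1L, 8L), c(3L, 10L)))
  pos <- initialConformation(10, 4, seed = 3)
  dir <- withr::local_tempdir()
  paths <- exportMdInputs(sys, pos, dir)
  g <- readGro(paths["gro"])
  expect_identical(as.integer(trimws(readLines(paths["gro"])[2])), 10L)
  expect_identical(g$labels, beadTypesToAnnotations(beadTypes(sys)))
  top <- parseTop(paths["top"])
  expect_identical(top$nBeads, 10L)
  expect_identical(top$beadTypes, beadTypes(sys))
  expect_identical(top$loops, unname(loops(sys)))
  expect_identical(top$bonds[, 2] - top$bonds[, 1], rep(1L, 9))
  expect_equal(top$typeMatrix, p@typeMatrix)
  expect_equal(top$idealGamma, p@idealGamma)
  # beads outside the confinement sphere only warn
  expect_warning(exportMdInputs(sys, pos + 10, withr::local_tempdir()),
                 "outside")
})
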