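#' @include AllClasses.R
NULL

#' Deterministic fixture generators
#'
#' Every synthetic input the test surface needs is generated by a pure
#' function of its arguments and a mandatory seed, and ships with the
#' closed-form or brute-force expectation its consumer asserts. All
#' generators are bit-reproducible under a fixed seed.
#'
#' @name fixtures
NULL

#' Two-type block copolymer system
#'
#' A chain of `nBeads` whose type sequence alternates between the supplied
#' labels in blocks of `blockLength`. When `blockLength` does not divide
#' `nBeads`, the final block is the shorter remainder (documented edge
#' rule). Exercises the microphase-separation mechanism: homotypic
#' attraction drives segments of equal type to demix spatially.
#'
#' @param nBeads chain length.
#' @param blockLength beads per block.
#' @param types character vector of labels to alternate over (default
#'   `c("A1", "B1")`).
#' @param seed integer seed (kept for generator-signature uniformity; the
#'   construction is deterministic).
#' @param loops optional 2-column anchor matrix.
#' @param parameters a [MiChroMParameters-class].
#' @return A [ChromosomeSystem-class].
#' @examples
#' beadTypes(makeBlockCopolymer(20, 10, seed = 1))
#' @export
makeBlockCopolymer <- function(nBeads, blockLength, types = c("A1", "B1"),
                               seed = 1L, loops = NULL,
                               parameters = michromParameters()) {
  if (!all(types %in% annotationAlphabet()))
    stop("unknown type label: ",
         paste(setdiff(types, annotationAlphabet()), collapse = ", "))
  nblocks <- ceiling(nBeads / blockLength)
  labels <- rep(rep(types, length.out = nblocks), each = blockLength)[seq_len(nBeads)]
  chromosomeSystem(annotationsToBeadTypes(labels), loops = loops,
                   parameters = parameters)
}

#' Ideal (Gaussian) chain ensemble with closed-form internal distances
#'
#' Frames of cumulative Gaussian steps with per-step mean-squared length
#' `bondB^2`, so the mean-squared internal distance obeys the Gaussian
#' chain closed form `<R^2(s)> = s * bondB^2` in expectation — the
#' analytic oracle for ensemble statistics.
#'
#' @param nBeads beads per chain.
#' @param nFrames independent frames.
#' @param bondB root-mean-square step length.
#' @param seed integer seed.
#' @return A [ChromEnsemble-class] (not a time series).
#' @export
makeIdealChainEnsemble <- function(nBeads, nFrames, bondB = 1, seed = 1L) {
  stopifnot(nBeads >= 2L, nFrames >= 1L, bondB > 0)
  set.seed(seed)
  sdc <- bondB / sqrt(3)
  models <- lapply(seq_len(nFrames), function(k) {
    steps <- matrix(stats::rnorm(3L * (nBeads - 1L), sd = sdc),
                    nBeads - 1L, 3L)
    rbind(0, apply(steps, 2L, cumsum))
  })
  chromEnsemble(beadRecords(nBeads), models,
                header = list(title = "ideal chain ensemble"))
}

#' Planted-structure contact map with multiplicative noise
#'
#' A symmetric map with a planted two-compartment checkerboard on top of a
#' power-law genomic-distance decay: the expected entry is
#' `decay(|i - j|) * pWithin` for same-block pairs and
#' `decay(|i - j|) * pBetween` otherwise, with `decay(s) = 1 / (1 + s)`,
#' multiplied by symmetric i.i.d. lognormal noise `exp(noise * Z)`. The
#' planted labels are returned for scoring eigenvector recovery; with
#' `noise = 0` recovery is exact up to global sign, and with
#' `pWithin == pBetween` there is no recoverable structure.
#'
#' @param nLoci number of loci.
#' @param blocks number of alternating blocks (labels alternate A, B).
#' @param pWithin,pBetween same-block and cross-block contact levels,
#'   `0 <= pBetween < pWithin <= 1` (equality allowed for the null case).
#' @param noise lognormal noise scale (0 = noiseless).
#' @param seed integer seed.
#' @return list with `map` (a [ContactMap-class]) and `labels` (character
#'   `"A"`/`"B"` per locus).
#' @export
makeBlockContactMap <- function(nLoci, blocks, pWithin = 0.8, pBetween = 0.2,
                                noise = 0.2, seed = 1L) {
  if (!(pBetween >= 0 && pBetween <= pWithin && pWithin <= 1))
    stop("require 0 <= pBetween <= pWithin <= 1")
  set.seed(seed)
  block_len <- ceiling(nLoci / blocks)
  lab <- rep(rep(c("A", "B"), length.out = blocks), each = block_len)[seq_len(nLoci)]
  same <- outer(lab, lab, "==")
  s <- abs(outer(seq_len(nLoci), seq_len(nLoci), "-"))
  base <- ifelse(same, pWithin, pBetween) / (1 + s)
  if (noise > 0) {
    z <- matrix(stats::rnorm(nLoci^2), nLoci)
    z <- (z + t(z)) / sqrt(2)
    base <- base * exp(noise * z)
  }
  m <- (base + t(base)) / 2
  diag(m) <- max(m)
  list(map = newContactMap(m), labels = lab)
}

#' Constructed .bed track with exactly representable bin integrals
#'
#' Generates a standards-conformant `.bed` interval set (0-based
#' half-open) whose proportional-overlap bin integrals are exactly
#' representable in binary floating point: interval boundaries sit on
#' multiples of `resolution / 8` and scores are small integers, so every
#' contribution `score * overlap / resolution` is a dyadic rational. The
#' analytic per-bin expectation is returned alongside; overlapping
#' intervals are allowed and their contributions add (documented policy).
#'
#' @param nIntervals number of intervals to draw.
#' @param chromLength chromosome length (bp).
#' @param resolution bin width (bp; must be divisible by 8).
#' @param seed integer seed.
#' @param chrom chromosome label used in the `.bed` lines.
#' @return list with `intervals` (`data.frame`: `start`, `end`, `score`,
#'   0-based half-open), `bedLines` (character `.bed` rows), `expected`
#'   (exact per-bin integrals) and `nBins`.
#' @export
makeBedTrack <- function(nIntervals, chromLength, resolution = 50000,
                         seed = 1L, chrom = "chr1") {
  stopifnot(resolution %% 8 == 0, chromLength %% resolution == 0)
  set.seed(seed)
  unit <- resolution / 8
  nunits <- chromLength / unit
  starts <- sample.int(nunits - 1L, nIntervals, replace = TRUE) - 1L
  lens <- sample.int(12L, nIntervals, replace = TRUE)
  ends <- pmin(starts + lens, nunits)
  scores <- sample.int(8L, nIntervals, replace = TRUE)
  intervals <- data.frame(start = starts * unit, end = ends * unit,
                          score = scores)
  nbins <- as.integer(chromLength / resolution)
  expected <- numeric(nbins)
  for (k in seq_len(nIntervals)) {
    for (b in seq_len(nbins)) {
      lo <- (b - 1) * resolution; hi <- b * resolution
      ov <- max(0, min(intervals$end[k], hi) - max(intervals$start[k], lo))
      # ov is a multiple of resolution/8: the quotient is dyadic-exact
      expected[b] <- expected[b] + intervals$score[k] * (ov / resolution)
    }
  }
  bedLines <- sprintf("%s\t%d\t%d\tiv%d\t%d", chrom, intervals$start,
                      intervals$end, seq_len(nIntervals), intervals$score)
  list(intervals = intervals, bedLines = bedLines, expected = expected,
       nBins = nbins)
}

#' Randomised valid structural ensemble
#'
#' Draws a structurally valid ensemble — one or more CHROM chains with
#' consecutive 50-kb windows, optional unbound DNAELE particles, optional
#' loops, coordinates rounded to the text format's 3-decimal precision —
#' for round-trip property testing of the format ecosystem.
#'
#' @param nBeads CHROM beads per chain.
#' @param nModels number of frames.
#' @param nChains number of chromatin chains (labelled `"1M"`, `"1P"`,
#'   `"2M"`, ... maternal/paternal style for even counts).
#' @param nDnaele number of free DNAELE particles (their own single-record
#'   chains, unbound: genomic fields absent).
#' @param withLoops attach 1-2 random loops on the first chain.
#' @param withSpread populate the spatial-spread field.
#' @param seed integer seed.
#' @return A [ChromEnsemble-class].
#' @export
makeRandomEnsemble <- function(nBeads, nModels, seed, nChains = 1L,
                               nDnaele = 0L, withLoops = FALSE,
                               withSpread = FALSE) {
  set.seed(seed)
  codes <- annotationAlphabet()[1:6]
  chain_ids <- if (nChains == 1L) "1"
               else paste0(rep(seq_len(ceiling(nChains / 2)), each = 2L),
                           c("M", "P"))[seq_len(nChains)]
  recs <- list()
  idx <- 0L
  for (ch in chain_ids) {
    r <- beadRecords(nBeads, codes = sample(codes, nBeads, replace = TRUE),
                     chain_id = ch)
    r$element_index <- idx + seq_len(nBeads)
    if (withSpread) r$spread <- round(stats::runif(nBeads, 0, 2), 3L)
    idx <- idx + nBeads
    recs[[ch]] <- r
  }
  if (nDnaele > 0L) {
    for (k in seq_len(nDnaele)) {
      recs[[paste0("E", k)]] <- data.frame(
        element_type = "DNAELE", element_index = idx + 1L,
        code = sample(c("TF", "CH"), 1L), genetic_info = "",
        chain_id = paste0("E", k), within_chain_index = 1L,
        genomic_start = NA_integer_, genomic_end = NA_integer_,
        spread = NA_real_, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  records <- do.call(rbind, recs)
  n <- nrow(records)
  models <- lapply(seq_len(nModels), function(m)
    matrix(round(stats::runif(3L * n, -20, 20), 3L), n, 3L))
  loops <- NULL
  if (withLoops && nBeads >= 4L) {
    a <- sample(seq_len(nBeads - 2L), 1L)
    b <- sample((a + 1L):nBeads, 1L)
    loops <- data.frame(anchor_a = a, anchor_b = b,
                        loop_class = sample(c("COHESIN", "POLYCOMB"), 1L),
                        stringsAsFactors = FALSE)
  }
  chromEnsemble(records, models, loops = loops,
                header = list(title = "random fixture",
                              authors = "fixture generator",
                              assembly = "toy1", length_unit = "reduced"))
}
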