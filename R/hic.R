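#' @include AllClasses.R
NULL

#' In-silico Hi-C contact map from a structural ensemble
#'
#' Reports the frequency of spatial contact between every pair of loci
#' over the frames of an ensemble. Two contact definitions are offered
#' (which definition an experimental pipeline corresponds to is a matter
#' of convention, so both are exposed):
#'
#' * `"cutoff"` (default) — entry (i, j) is the fraction of frames with
#'   `r_ij <= rc`;
#' * `"kernel"` — entry (i, j) is the mean of the sigmoidal contact
#'   kernel `f(r_ij)` over frames (see [contactKernel()]).
#'
#' @param ensemble a [ChromEnsemble-class] with at least one frame.
#' @param rc contact cutoff / kernel midpoint (default the model's
#'   `contactRc`, 1.78 reduced units).
#' @param mode `"cutoff"` or `"kernel"`.
#' @param mu kernel steepness for `"kernel"` mode.
#' @param resolution,chrom metadata for the result (defaults read from the
#'   ensemble records).
#' @return A [ContactMap-class].
#' @export
contactMap <- function(ensemble, rc = 1.78, mode = c("cutoff", "kernel"),
                       mu = 3.22, resolution = NULL, chrom = NULL) {
  mode <- match.arg(mode)
  validObject(ensemble)
  if (length(ensemble@models) == 0L) stop("empty ensemble")
  if (rc <= 0) stop("rc must be positive")
  n <- nrow(ensemble@records)
  F <- length(ensemble@models)
  frames <- array(unlist(ensemble@models), dim = c(n, 3L, F))
  m <- .cppContactMap(as.vector(frames), n, F, rc, mode == "kernel", mu)
  if (is.null(resolution)) {
    gs <- ensemble@records$genomic_start
    ge <- ensemble@records$genomic_end
    resolution <- if (all(!is.na(c(gs[1L], ge[1L])))) ge[1L] - gs[1L] + 1L
                  else 50000
  }
  if (is.null(chrom)) chrom <- ensemble@records$chain_id[1L]
  newContactMap(m, resolution = resolution, chrom = chrom, nFramesUsed = F)
}

#' Contact probability versus genomic distance, P(s)
#'
#' `P(s)` is the mean of the map entries at genomic separation `s` beads,
#' for `s = 1 .. n - 1`. The decay is reported as observed, never
#' enforced.
#'
#' @param map a [ContactMap-class].
#' @return `data.frame` with columns `s` (bead separation), `distance_bp`
#'   and `p`.
#' @export
psCurve <- function(map) {
  m <- map@matrix
  n <- nrow(m)
  s <- seq_len(n - 1L)
  d <- row(m) - col(m)
  p <- vapply(s, function(k) mean(m[d == k]), numeric(1))
  data.frame(s = s, distance_bp = s * map@resolution, p = p)
}

# observed / expected with expected = per-diagonal mean
.observedExpected <- function(m) {
  n <- nrow(m)
  d <- abs(row(m) - col(m))
  expected <- vapply(0:(n - 1L), function(k) mean(m[d == k]), numeric(1))
  e <- expected[d + 1L]
  oe <- m / e
  oe[e == 0] <- 0
  oe
}

#' Compartment profile: first eigenvector of the Pearson matrix
#'
#' The standard compartment-calling pipeline: the map is normalised
#' observed/expected (expected = per-diagonal mean), the Pearson
#' correlation matrix of its columns is formed, and the leading
#' eigenvector is extracted. Positive and negative entries partition the
#' loci into the two spatial compartments that produce the plaid pattern
#' of a Hi-C map. Masked loci (all-zero rows, e.g. centromeres) are
#' excluded from the correlation matrix and re-inserted as `NA`.
#'
#' The global sign of an eigenvector is arbitrary. When `annotations` are
#' supplied, the vector is oriented so that A-class loci have positive
#' mean; otherwise the component of largest magnitude is made positive.
#' The rule applied is recorded in the profile's `signConvention`.
#'
#' @param map a [ContactMap-class] with at least 3 unmasked loci.
#' @param annotations optional [AnnotationSequence-class] or character
#'   labels used only to orient the sign.
#' @return A [CompartmentProfile-class].
#' @export
compartmentEigenvector <- function(map, annotations = NULL) {
  m <- map@matrix
  n <- nrow(m)
  mask <- rowSums(m) > 0 & apply(m, 1L, function(r) stats::var(r) > 0)
  if (sum(mask) < 3L)
    stop("degenerate map: fewer than 3 loci with non-constant nonzero rows")
  oe <- .observedExpected(m[mask, mask, drop = FALSE])
  sds <- apply(oe, 2L, stats::sd)
  if (all(sds == 0))
    stop("degenerate map: observed/expected matrix is constant")
  keep <- sds > 0
  if (sum(keep) < 3L)
    stop("degenerate map: fewer than 3 non-constant observed/expected columns")
  cc <- stats::cor(oe[keep, keep, drop = FALSE])
  eig <- eigen(cc, symmetric = TRUE)
  v <- eig$vectors[, 1L]
  share <- abs(eig$values[1L]) / sum(abs(eig$values))
  full <- rep(NA_real_, n)
  idx <- which(mask)[keep]
  full[idx] <- v
  if (!is.null(annotations)) {
    labels <- if (is(annotations, "AnnotationSequence")) annotations@labels
              else as.character(annotations)
    a_mean <- mean(full[startsWith(labels, "A")], na.rm = TRUE)
    sgn <- if (is.finite(a_mean) && a_mean < 0) -1 else 1
    convention <- "A-class loci oriented positive using supplied annotations"
  } else {
    sgn <- if (v[which.max(abs(v))] < 0) -1 else 1
    convention <- "largest-magnitude component oriented positive"
  }
  full <- full * sgn
  # renormalise to unit norm over unmasked entries (numerical safety)
  nv <- sqrt(sum(full[!is.na(full)]^2))
  full[!is.na(full)] <- full[!is.na(full)] / nv
  new("CompartmentProfile", eigenvector = full,
      signConvention = convention, explainedShare = share)
}

#' Pearson correlation between two compartment profiles
#'
#' Computed over loci unmasked in both profiles, after optimal global sign
#' alignment (eigenvector signs are arbitrary); the sign used is reported.
#'
#' @param a,b [CompartmentProfile-class] objects (or numeric vectors) of
#'   equal length with at least 3 shared unmasked loci.
#' @return list with `r` (Pearson correlation after alignment) and `sign`
#'   (+1 or -1, the factor applied to `b`).
#' @export
compareEigenvectors <- function(a, b) {
  va <- if (is(a, "CompartmentProfile")) a@eigenvector else as.numeric(a)
  vb <- if (is(b, "CompartmentProfile")) b@eigenvector else as.numeric(b)
  if (length(va) != length(vb)) stop("profiles must have equal length")
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3L) stop("fewer than 3 shared unmasked loci")
  r <- stats::cor(va[ok], vb[ok])
  sgn <- if (r < 0) -1 else 1
  list(r = r * sgn, sign = sgn)
}

#' Distance-stratified Pearson correlation between two maps
#'
#' For each genomic separation `s`, the Pearson correlation between the
#' s-th diagonals of the two maps. Constant diagonals have no defined
#' correlation and are reported as `NA`. Maps of unequal size can be
#' compared with `truncate = TRUE`, which crops both to the common upper
#' left block — the paper-style null comparison between different
#' chromosomes.
#'
#' @param a,b [ContactMap-class] objects (or plain matrices).
#' @param maxS largest separation to report (default `n - 2`).
#' @param truncate crop to common size rather than erroring on a size
#'   mismatch.
#' @return `data.frame` with columns `s` and `r`.
#' @export
mapCorrelationByDistance <- function(a, b, maxS = NULL, truncate = FALSE) {
  ma <- if (is(a, "ContactMap")) a@matrix else as.matrix(a)
  mb <- if (is(b, "ContactMap")) b@matrix else as.matrix(b)
  if (nrow(ma) != nrow(mb)) {
    if (!truncate) stop("maps differ in size (use truncate = TRUE to crop)")
    n <- min(nrow(ma), nrow(mb))
    ma <- ma[seq_len(n), seq_len(n)]
    mb <- mb[seq_len(n), seq_len(n)]
  }
  n <- nrow(ma)
  if (is.null(maxS)) maxS <- n - 2L
  maxS <- min(maxS, n - 2L)
  d <- row(ma) - col(ma)
  res <- vapply(seq_len(maxS), function(s) {
    da <- ma[d == s]; db <- mb[d == s]
    if (length(da) < 2L || stats::sd(da) == 0 || stats::sd(db) == 0)
      NA_real_
    else stats::cor(da, db)
  }, numeric(1))
  data.frame(s = seq_len(maxS), r = res)
}

#' FISH-style pairwise distance distribution
#'
#' The per-frame spatial distance between two loci over the ensemble —
#' the computational counterpart of the distance distribution monitored by
#' fluorescence in-situ hybridisation — with summary statistics and a
#' histogram.
#'
#' @param ensemble a [ChromEnsemble-class].
#' @param i,j locus (record row) indices.
#' @param breaks histogram breaks passed to [graphics::hist()] semantics
#'   via [base::cut()]; default 30 equal-width bins.
#' @return list with `samples` (per-frame distances), `mean`, `median`,
#'   `quantiles` (5%, 25%, 75%, 95%) and `histogram`
#'   (`data.frame` of bin mids and counts).
#' @export
distanceDistribution <- function(ensemble, i, j, breaks = 30L) {
  validObject(ensemble)
  n <- nrow(ensemble@records)
  if (i < 1L || i > n || j < 1L || j > n) stop("locus index out of range")
  if (i == j) {
    warning("i == j: the distance distribution is identically zero")
    samples <- rep(0, length(ensemble@models))
  } else {
    samples <- vapply(ensemble@models, function(m)
      sqrt(sum((m[i, ] - m[j, ])^2)), numeric(1))
  }
  rng <- range(samples)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = breaks + 1L)
  counts <- tabulate(cut(samples, edges, include.lowest = TRUE),
                     nbins = breaks)
  list(samples = samples,
       mean = mean(samples), median = stats::median(samples),
       quantiles = stats::quantile(samples, c(0.05, 0.25, 0.75, 0.95)),
       histogram = data.frame(mid = (edges[-1L] + edges[-(breaks + 1L)]) / 2,
                              count = counts))
}
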