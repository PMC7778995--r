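#' @include AllClasses.R
NULL

#' Integrate a .bed signal track over fixed-width bins
#'
#' Each bin's value is the length-weighted integral of the interval scores:
#' an interval contributes `score * overlap_bp / resolution` to every bin
#' it overlaps, so the integral is exact and independent of how intervals
#' split across bin boundaries, and total signal is conserved
#' (`sum(bins) = sum(score * length) / resolution`).
#'
#' `.bed` input follows the standard 0-based half-open convention; it is
#' converted to 1-based inclusive coordinates at ingest (all internal and
#' `.ndb` coordinates are 1-based inclusive). Intervals extending beyond
#' `chromLength` are clipped with a warning; negative scores are an error.
#'
#' @param bed a `.bed` file path, a `GRanges` with a `score` column, or a
#'   `data.frame` with columns `start`, `end` (0-based half-open) and
#'   `score`.
#' @param chromLength chromosome length in bp.
#' @param resolution bin width in bp (default 50000).
#' @param mark mark name to attach to the track.
#' @param chrom chromosome label to attach.
#' @return A [BinnedTrack-class] with `ceiling(chromLength / resolution)`
#'   bins.
#' @examples
#' bed <- data.frame(start = 25000, end = 75000, score = 4)
#' trackValues(binBedSignal(bed, chromLength = 150000))  # 2, 2, 0
#' @export
binBedSignal <- function(bed, chromLength, resolution = 50000,
                         mark = "signal", chrom = "1") {
  if (is.character(bed)) {
    gr <- rtracklayer::import(bed, format = "BED")
    if (!"score" %in% names(S4Vectors::mcols(gr)) ||
        all(is.na(S4Vectors::mcols(gr)$score)))
      stop("the .bed file carries no score column")
  } else if (is(bed, "GRanges")) {
    gr <- bed
  } else {
    bed <- as.data.frame(bed)
    gr <- GenomicRanges::GRanges(
      seqnames = rep(chrom, nrow(bed)),
      ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
      score = bed$score)
  }
  nbins <- as.integer(ceiling(chromLength / resolution))
  if (length(gr) == 0L)
    return(binnedTrack(mark, chrom, numeric(nbins), resolution))
  score <- S4Vectors::mcols(gr)$score
  if (any(score < 0)) stop("negative interval score")
  if (any(GenomicRanges::end(gr) > chromLength) ||
      any(GenomicRanges::start(gr) < 1L)) {
    warning("intervals beyond chromosome bounds were clipped")
    gr <- IRanges::restrict(gr, start = 1L, end = as.integer(chromLength))
    keep <- GenomicRanges::width(gr) > 0L
    gr <- gr[keep]; score <- score[keep]
  }
  bins <- GenomicRanges::GRanges(
    seqnames = unique(as.character(GenomicRanges::seqnames(gr)))[1L],
    ranges = IRanges::IRanges(
      start = (seq_len(nbins) - 1L) * resolution + 1L,
      end = pmin(seq_len(nbins) * resolution, as.integer(chromLength))))
  hits <- GenomicRanges::findOverlaps(gr, bins, ignore.strand = TRUE)
  ov <- IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                            bins[S4Vectors::subjectHits(hits)],
                            ignore.strand = TRUE)
  contrib <- score[S4Vectors::queryHits(hits)] *
    GenomicRanges::width(ov) / resolution
  values <- numeric(nbins)
  agg <- tapply(contrib, S4Vectors::subjectHits(hits), sum)
  values[as.integer(names(agg))] <- as.numeric(agg)
  binnedTrack(mark, chrom, values, resolution)
}

#' Assemble the bins-by-marks feature matrix
#'
#' Stacks binned tracks into a matrix whose columns follow the canonical
#' 11-mark order ([canonicalMarks()]); user-defined marks follow in
#' alphabetical order. Missing canonical marks are allowed — prediction can
#' run on a subset of the tracks — and are reported in the
#' `missing_marks` attribute.
#'
#' @param tracks list of [BinnedTrack-class] objects sharing chromosome
#'   label, resolution and bin count.
#' @return Numeric bins-by-marks matrix with column names, with attribute
#'   `missing_marks`.
#' @export
collectMarks <- function(tracks) {
  if (length(tracks) == 0L) stop("no tracks supplied")
  chroms <- vapply(tracks, slot, character(1), "chrom")
  res <- vapply(tracks, slot, numeric(1), "resolution")
  lens <- vapply(tracks, function(t) length(t@values), integer(1))
  if (length(unique(chroms)) != 1L)
    stop("all tracks must share the same chromosome label")
  if (length(unique(res)) != 1L)
    stop("all tracks must share the same resolution")
  if (length(unique(lens)) != 1L)
    stop("all tracks must share the same bin count")
  marks <- vapply(tracks, slot, character(1), "mark")
  if (anyDuplicated(marks)) stop("duplicate mark names")
  canon <- intersect(canonicalMarks(), marks)
  extra <- sort(setdiff(marks, canonicalMarks()))
  ord <- match(c(canon, extra), marks)
  m <- do.call(cbind, lapply(tracks[ord], slot, "values"))
  colnames(m) <- marks[ord]
  attr(m, "missing_marks") <- setdiff(canonicalMarks(), marks)
  m
}

#' Predict subcompartment annotations from a feature matrix
#'
#' Applies a pluggable predictor satisfying the bins-by-marks to labels
#' contract. The shipped default, [baselinePredictor()], is a transparent
#' documented heuristic contrasting active against repressive marks — a
#' pipeline baseline, not a reimplementation of a trained
#' epigenetics-to-subcompartment network (whose weights are external to
#' this package). A user-supplied annotation file can bypass prediction
#' entirely (see [readAnnotations()]).
#'
#' @param featureMatrix bins-by-marks numeric matrix (see
#'   [collectMarks()]).
#' @param predictor a function `matrix -> character vector` of labels over
#'   [annotationAlphabet()].
#' @param chrom,resolution metadata for the returned sequence.
#' @return An [AnnotationSequence-class], one label per bin.
#' @export
predictAnnotations <- function(featureMatrix, predictor = baselinePredictor,
                               chrom = "1", resolution = 50000) {
  labels <- predictor(featureMatrix)
  if (length(labels) != nrow(featureMatrix))
    stop("predictor must return one label per bin")
  bad <- setdiff(unique(labels), annotationAlphabet())
  if (length(bad))
    stop("predictor emitted labels outside the annotation alphabet: ",
         paste(bad, collapse = ", "))
  annotationSequence(labels, chrom = chrom, resolution = resolution)
}

#' Baseline active-versus-repressive annotation heuristic
#'
#' A deliberately simple, fully documented rule so the pipeline runs end
#' to end without external trained weights:
#'
#' 1. Bins with zero total signal are labelled `B3` (the default quiescent
#'    class).
#' 2. Each mark is scaled by its mean over non-zero bins; the active score
#'    is the mean of the scaled activating marks (H2AFZ, H3K27ac, H3K4me1,
#'    H3K4me2, H3K4me3, H3K9ac, H3K36me3, H3K79me2), the repressive score
#'    the mean of the scaled repressive marks (H3K27me3, H3K9me3,
#'    H4K20me1).
#' 3. Active > repressive: `A1` when the promoter-proximal mark H3K4me3
#'    dominates H3K4me1, else `A2`. Otherwise: `B1` when H3K27me3
#'    dominates H3K9me3, else `B3`.
#'
#' The heuristic never emits `B2` or `B4`.
#'
#' @param featureMatrix bins-by-marks numeric matrix with mark column
#'   names.
#' @return Character vector of labels, one per bin.
#' @export
baselinePredictor <- function(featureMatrix) {
  m <- as.matrix(featureMatrix)
  n <- nrow(m)
  active_marks <- c("H2AFZ", "H3K27ac", "H3K4me1", "H3K4me2", "H3K4me3",
                    "H3K9ac", "H3K36me3", "H3K79me2")
  repr_marks <- c("H3K27me3", "H3K9me3", "H4K20me1")
  scale1 <- function(v) {
    mu <- mean(v[v > 0])
    if (!is.finite(mu) || mu == 0) v else v / mu
  }
  ms <- apply(m, 2L, scale1)
  if (is.null(dim(ms))) ms <- matrix(ms, nrow = n)
  colnames(ms) <- colnames(m)
  rowMeanOf <- function(cols) {
    cols <- intersect(cols, colnames(ms))
    if (!length(cols)) return(numeric(n))
    rowMeans(ms[, cols, drop = FALSE])
  }
  act <- rowMeanOf(active_marks)
  rep_ <- rowMeanOf(repr_marks)
  getcol <- function(nm) if (nm %in% colnames(ms)) ms[, nm] else numeric(n)
  k4me3 <- getcol("H3K4me3"); k4me1 <- getcol("H3K4me1")
  k27 <- getcol("H3K27me3"); k9 <- getcol("H3K9me3")
  labels <- ifelse(act > rep_,
                   ifelse(k4me3 >= k4me1, "A1", "A2"),
                   ifelse(k27 > k9, "B1", "B3"))
  labels[rowSums(m) == 0] <- "B3"
  labels
}

#' Read a per-locus annotation text file
#'
#' One label per 50-kb line, the layout of per-chromosome annotation
#' folders (`C1` .. `C22`). Lines holding anything outside the alphabet
#' are treated as `NA` (centromere/unannotated).
#'
#' @param path text file with one label per line.
#' @param chrom,resolution metadata for the returned sequence.
#' @return An [AnnotationSequence-class].
#' @export
readAnnotations <- function(path, chrom = "1", resolution = 50000) {
  labels <- trimws(readLines(path))
  labels <- labels[nzchar(labels)]
  labels[!labels %in% annotationAlphabet()] <- "NA"
  annotationSequence(labels, chrom = chrom, resolution = resolution)
}

#' Map annotations to bead type indices and back
#'
#' The bijection A1, A2, B1, B2, B3, B4 to 0..5, with the neutral
#' centromere/`NA` label mapped to the dedicated type 6 (zero type-type
#' coupling).
#'
#' @param annotations an [AnnotationSequence-class] or character vector.
#' @return `annotationsToBeadTypes()`: integer vector of type indices.
#' @export
annotationsToBeadTypes <- function(annotations) {
  labels <- if (is(annotations, "AnnotationSequence")) annotations@labels
            else as.character(annotations)
  labels[is.na(labels)] <- "NA"
  idx <- match(labels, .TYPE_LABELS) - 1L
  if (anyNA(idx))
    stop("labels outside the annotation alphabet: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

#' @rdname annotationsToBeadTypes
#' @param types integer type indices in 0..6.
#' @return `beadTypesToAnnotations()`: character vector of labels.
#' @export
beadTypesToAnnotations <- function(types) {
  types <- as.integer(types)
  if (any(types < 0L | types > 6L)) stop("type indices must lie in 0..6")
  .TYPE_LABELS[types + 1L]
}

#' Overlay a 1D signal or annotation onto a 3D structure
#'
#' Computes a per-bead scalar and colour assignment for one of three
#' colouring schemes:
#'
#' * `"index"` — genomic position along the polymer, a monotone gradient
#'   from head to tail (red to blue);
#' * `"compartment"` — categorical: A-class loci orange, B-class green,
#'   centromeric/neutral pink;
#' * `"track"` — continuous, proportional to the integrated ChIP-seq
#'   signal of `track`.
#'
#' @param ensemble a [ChromEnsemble-class].
#' @param colorSpec one of `"index"`, `"compartment"`, `"track"`.
#' @param track a [BinnedTrack-class] (required for `"track"`); its bins
#'   must align with the ensemble beads (same count).
#' @param annotations optional [AnnotationSequence-class] or character
#'   vector overriding the record codes for `"compartment"`.
#' @return `data.frame` with columns `bead`, `value` and `color` (hex).
#' @export
overlayTrack <- function(ensemble, colorSpec = c("index", "compartment", "track"),
                         track = NULL, annotations = NULL) {
  colorSpec <- match.arg(colorSpec)
  validObject(ensemble)
  n <- nrow(ensemble@records)
  if (colorSpec == "index") {
    value <- seq_len(n)
    pal <- grDevices::colorRampPalette(c("red", "blue"))(n)
    color <- pal
  } else if (colorSpec == "compartment") {
    labels <- if (is.null(annotations)) ensemble@records$code
              else if (is(annotations, "AnnotationSequence")) annotations@labels
              else as.character(annotations)
    if (length(labels) != n) stop("annotation length must equal bead count")
    cls <- ifelse(startsWith(labels, "A"), "A",
                  ifelse(startsWith(labels, "B"), "B", "NA"))
    value <- match(cls, c("A", "B", "NA"))
    color <- c(A = "#FFA500", B = "#008000", "NA" = "#FFC0CB")[cls]
  } else {
    if (is.null(track)) stop("colorSpec 'track' requires a track")
    v <- track@values
    if (length(v) != n)
      stop(sprintf("track has %d bins but the ensemble has %d beads",
                   length(v), n))
    value <- v
    rng <- range(v)
    t <- if (diff(rng) == 0) rep(0, n) else (v - rng[1L]) / diff(rng)
    pal <- grDevices::colorRamp(c("white", "darkgreen"))(t)
    color <- grDevices::rgb(pal[, 1L], pal[, 2L], pal[, 3L],
                            maxColorValue = 255)
  }
  data.frame(bead = seq_len(n), value = as.numeric(value), color = unname(color),
             stringsAsFactors = FALSE)
}
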