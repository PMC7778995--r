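#' @include NucleomeSim-package.R
NULL

## Canonical alphabets --------------------------------------------------------

#' Subcompartment annotation alphabet
#'
#' The six two-letter subcompartment codes plus the neutral label `"NA"`
#' used for centromeric/unannotated loci.
#'
#' @return Character vector of valid annotation labels.
#' @export
annotationAlphabet <- function() c("A1", "A2", "B1", "B2", "B3", "B4", "NA")

#' Canonical ChIP-seq mark order
#'
#' The eleven histone-modification tracks used for subcompartment
#' prediction, in the canonical column order of the feature matrix.
#'
#' @return Character vector of the 11 mark names.
#' @export
canonicalMarks <- function() {
  c("H2AFZ", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me2",
    "H3K4me3", "H3K79me2", "H3K9ac", "H3K9me3", "H4K20me1")
}

.LOOP_CLASSES <- c("COHESIN", "POLYCOMB", "UNKNOWN")

## ChromEnsemble ---------------------------------------------------------------

#' Structural ensemble of one or more chromosome models
#'
#' An ordered set of coordinate frames (models) over a fixed set of nuclear
#' elements, together with header metadata and a stable-loop list. Each
#' element is either a `CHROM` bead (a 50-kb chromatin segment, by default)
#' or a `DNAELE` particle (any other DNA-associated element, e.g. a
#' transcription factor `TF` or cohesin `CH`). Per-element metadata are
#' shared across frames; only coordinates vary.
#'
#' The `records` slot is a `data.frame` with one row per element and
#' columns `element_type`, `element_index`, `code`, `genetic_info`,
#' `chain_id`, `within_chain_index`, `genomic_start`, `genomic_end`,
#' `spread`. Genomic coordinates are 1-based inclusive base pairs; `NA`
#' means absent/unbound. `spread` reports the width of the spatial
#' distribution of a locus in optical experiments (the format description
#' also calls this the variance of that distribution; the value is stored
#' verbatim).
#'
#' @slot header list with elements `title`, `authors` (character vector),
#'   `assembly`, `length_unit`, `compartment_sequence` (named list, one
#'   character vector of two-letter codes per chain), `model_count`, and
#'   optional `diagnostics`.
#' @slot records per-element metadata `data.frame` (see Details).
#' @slot models list of numeric n-by-3 coordinate matrices, one per frame.
#' @slot loops `data.frame` with columns `anchor_a`, `anchor_b` (element
#'   indices, field 2) and `loop_class` (`COHESIN`, `POLYCOMB` or
#'   `UNKNOWN`).
#' @slot isTimeSeries logical; `TRUE` when the frames form a dynamical
#'   trajectory rather than independent samples.
#'
#' @seealso [chromEnsemble()], [readNdb()], [writeNdb()]
#' @export
setClass("ChromEnsemble",
  representation(
    header = "list",
    records = "data.frame",
    models = "list",
    loops = "data.frame",
    isTimeSeries = "logical"
  )
)

.validChromEnsemble <- function(object) {
  msg <- character()
  rec <- object@records
  need <- c("element_type", "element_index", "code", "genetic_info",
            "chain_id", "within_chain_index", "genomic_start",
            "genomic_end", "spread")
  if (!all(need %in% names(rec)))
    return(paste("records is missing columns:",
                 paste(setdiff(need, names(rec)), collapse = ", ")))
  n <- nrow(rec)
  if (n == 0L) msg <- c(msg, "ensemble has no records")
  if (length(object@models) == 0L) msg <- c(msg, "ensemble has no models")
  for (m in object@models) {
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n) {
      msg <- c(msg, "every model must be an n-by-3 coordinate matrix matching the record count")
      break
    }
  }
  if (!all(rec$element_type %in% c("CHROM", "DNAELE")))
    msg <- c(msg, "element_type must be CHROM or DNAELE")
  bad <- !is.na(rec$genomic_start) & !is.na(rec$genomic_end) &
    rec$genomic_end < rec$genomic_start
  if (any(bad))
    msg <- c(msg, sprintf("genomic_end < genomic_start for element index %d",
                          rec$element_index[which(bad)[1L]]))
  for (ch in unique(rec$chain_id)) {
    idx <- rec$within_chain_index[rec$chain_id == ch]
    if (any(diff(idx) <= 0))
      msg <- c(msg, sprintf("within_chain_index not strictly increasing in chain %s", ch))
    typ <- rec$element_type[rec$chain_id == ch]
    if (any(typ == "DNAELE") && length(typ) > 1L)
      msg <- c(msg, sprintf("DNAELE chain %s must contain exactly one record", ch))
  }
  if (nrow(object@loops)) {
    lp <- object@loops
    if (!all(c("anchor_a", "anchor_b", "loop_class") %in% names(lp)))
      msg <- c(msg, "loops must have columns anchor_a, anchor_b, loop_class")
    else {
      if (any(lp$anchor_a == lp$anchor_b))
        msg <- c(msg, "loop anchors must be distinct")
      chrom_idx <- rec$element_index[rec$element_type == "CHROM"]
      if (!all(c(lp$anchor_a, lp$anchor_b) %in% chrom_idx))
        msg <- c(msg, "loop anchors must reference existing CHROM element indices")
      if (!all(lp$loop_class %in% .LOOP_CLASSES))
        msg <- c(msg, "loop_class must be COHESIN, POLYCOMB or UNKNOWN")
    }
  }
  hdr <- object@header
  if (is.null(hdr$length_unit) || !nzchar(hdr$length_unit))
    msg <- c(msg, "header length_unit must be non-empty")
  if (!is.null(hdr$model_count) && hdr$model_count != length(object@models))
    msg <- c(msg, "header model_count disagrees with the number of models")
  cs <- hdr$compartment_sequence
  if (!is.null(cs)) {
    for (ch in names(cs)) {
      nch <- sum(rec$chain_id == ch & rec$element_type == "CHROM")
      if (length(cs[[ch]]) != nch)
        msg <- c(msg, sprintf(
          "compartment_sequence for chain %s has length %d but the chain has %d CHROM records",
          ch, length(cs[[ch]]), nch))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ChromEnsemble", .validChromEnsemble)

#' Construct a structural ensemble
#'
#' @param records per-element metadata `data.frame`; see
#'   [ChromEnsemble-class]. Missing optional columns (`genetic_info`,
#'   `genomic_start`, `genomic_end`, `spread`) are filled with `NA`/empty.
#' @param models list of n-by-3 coordinate matrices (or a single matrix).
#' @param loops optional loop `data.frame` (`anchor_a`, `anchor_b`,
#'   `loop_class`).
#' @param header optional named list; `title`, `authors`, `assembly`,
#'   `length_unit` (default `"reduced"`). `model_count` and
#'   `compartment_sequence` are derived from the data.
#' @param isTimeSeries logical flag.
#' @return A validated [ChromEnsemble-class] object.
#' @examples
#' rec <- beadRecords(5)
#' e <- chromEnsemble(rec, list(matrix(rnorm(15), 5, 3)))
#' nModels(e)
#' @export
chromEnsemble <- function(records, models, loops = NULL, header = list(),
                          isTimeSeries = FALSE) {
  if (is.matrix(models)) models <- list(models)
  models <- lapply(models, function(m) {
    m <- unname(as.matrix(m))
    storage.mode(m) <- "double"
    m
  })
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$genetic_info)) records$genetic_info <- ""
  if (is.null(records$genomic_start)) records$genomic_start <- NA_integer_
  if (is.null(records$genomic_end)) records$genomic_end <- NA_integer_
  if (is.null(records$spread)) records$spread <- NA_real_
  records$element_index <- as.integer(records$element_index)
  records$within_chain_index <- as.integer(records$within_chain_index)
  records$genomic_start <- as.integer(records$genomic_start)
  records$genomic_end <- as.integer(records$genomic_end)
  records$spread <- as.numeric(records$spread)
  rownames(records) <- NULL
  if (is.null(loops))
    loops <- data.frame(anchor_a = integer(), anchor_b = integer(),
                        loop_class = character(), stringsAsFactors = FALSE)
  loops <- as.data.frame(loops, stringsAsFactors = FALSE)
  if (nrow(loops)) {
    loops$anchor_a <- as.integer(loops$anchor_a)
    loops$anchor_b <- as.integer(loops$anchor_b)
    if (is.null(loops$loop_class)) loops$loop_class <- "UNKNOWN"
    loops$loop_class <- as.character(loops$loop_class)
  }
  rownames(loops) <- NULL
  hdr <- list(
    title = if (is.null(header$title)) "" else header$title,
    authors = if (is.null(header$authors)) character() else as.character(header$authors),
    assembly = if (is.null(header$assembly)) "" else header$assembly,
    length_unit = if (is.null(header$length_unit)) "reduced" else header$length_unit,
    model_count = length(models),
    compartment_sequence = .deriveCompartmentSequence(records)
  )
  if (!is.null(header$diagnostics)) hdr$diagnostics <- header$diagnostics
  new("ChromEnsemble", header = hdr, records = records, models = models,
      loops = loops, isTimeSeries = isTimeSeries)
}

.deriveCompartmentSequence <- function(records) {
  chrom <- records[records$element_type == "CHROM", , drop = FALSE]
  chains <- unique(chrom$chain_id)
  setNames(lapply(chains, function(ch) chrom$code[chrom$chain_id == ch]), chains)
}

#' Default CHROM bead records for a single chain
#'
#' Convenience constructor for the common case of one chromatin chain of
#' `n` beads at a fixed resolution.
#'
#' @param n number of beads.
#' @param codes annotation codes, recycled to length `n` (default `"A1"`).
#' @param chain_id chain label (e.g. `"12"`, `"1M"`).
#' @param resolution bead size in base pairs (default 50000); genomic
#'   coordinates are assigned as consecutive 1-based inclusive windows.
#' @return A records `data.frame` suitable for [chromEnsemble()].
#' @export
beadRecords <- function(n, codes = "A1", chain_id = "1", resolution = 50000L) {
  codes <- rep_len(as.character(codes), n)
  data.frame(
    element_type = rep("CHROM", n),
    element_index = seq_len(n),
    code = codes,
    genetic_info = "",
    chain_id = rep(as.character(chain_id), n),
    within_chain_index = seq_len(n),
    genomic_start = as.integer((seq_len(n) - 1L) * resolution + 1L),
    genomic_end = as.integer(seq_len(n) * resolution),
    spread = NA_real_,
    stringsAsFactors = FALSE
  )
}

## BinnedTrack -----------------------------------------------------------------

#' A 50-kb binned ChIP-seq signal track
#'
#' Scalar signal per fixed-width genomic bin on one chromosome, produced by
#' length-weighted integration of a `.bed` interval track
#' (see [binBedSignal()]).
#'
#' @slot mark mark name (one of [canonicalMarks()] or user-defined).
#' @slot chrom chromosome label.
#' @slot resolution bin width in base pairs.
#' @slot values non-negative numeric, one value per bin.
#' @export
setClass("BinnedTrack",
  representation(mark = "character", chrom = "character",
                 resolution = "numeric", values = "numeric")
)
setValidity("BinnedTrack", function(object) {
  msg <- character()
  if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (any(object@values < 0)) msg <- c(msg, "values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname BinnedTrack-class
#' @param mark,chrom,resolution,values slot values; see slots above.
#' @return A [BinnedTrack-class] object.
#' @export
binnedTrack <- function(mark, chrom, values, resolution = 50000) {
  new("BinnedTrack", mark = as.character(mark), chrom = as.character(chrom),
      resolution = as.numeric(resolution), values = as.numeric(values))
}

## AnnotationSequence ----------------------------------------------------------

#' Per-bin subcompartment annotation sequence
#'
#' One label per fixed-width bin, drawn from the subcompartment alphabet
#' A1, A2, B1, B2, B3, B4 plus `"NA"` for centromeric/unannotated loci.
#'
#' @slot chrom chromosome label.
#' @slot resolution bin width in base pairs.
#' @slot labels character vector over [annotationAlphabet()].
#' @export
setClass("AnnotationSequence",
  representation(chrom = "character", resolution = "numeric",
                 labels = "character")
)
setValidity("AnnotationSequence", function(object) {
  if (!all(object@labels %in% annotationAlphabet()))
    paste("labels outside the annotation alphabet:",
          paste(unique(setdiff(object@labels, annotationAlphabet())), collapse = ", "))
  else TRUE
})

#' @rdname AnnotationSequence-class
#' @param chrom,resolution,labels slot values.
#' @return An [AnnotationSequence-class] object.
#' @export
annotationSequence <- function(labels, chrom = "1", resolution = 50000) {
  labels <- as.character(labels)
  labels[is.na(labels)] <- "NA"
  new("AnnotationSequence", chrom = as.character(chrom),
      resolution = as.numeric(resolution), labels = labels)
}

## MiChroMParameters -----------------------------------------------------------

#' Coefficients of the chromatin energy function
#'
#' All coefficients of the MiChroM-style energy landscape, in reduced units
#' (bead diameter sigma = 1, thermal energy = 1). See
#' [michromParameters()] for defaults and meanings.
#'
#' @slot feneK,feneR0 FENE bond stiffness (energy/length^2) and maximum
#'   extension (length).
#' @slot stericEpsilon,stericSigma soft-core repulsion scale (energy) and
#'   range (length).
#' @slot confinementRadius,confinementK spherical wall radius (length) and
#'   stiffness (energy/length^2).
#' @slot typeMatrix symmetric 7x7 coupling matrix alpha(t, t') over the
#'   type alphabet A1,A2,B1,B2,B3,B4 plus the neutral centromere type.
#' @slot idealGamma three coefficients (g1, g2, g3) of the genomic-distance
#'   kernel gamma(d) = g1/log(d) + g2/d + g3/d^2.
#' @slot dMin,dMax genomic-separation cutoffs (beads) of the
#'   ideal-chromosome term.
#' @slot loopChi loop interaction strength (negative = attractive).
#' @slot contactMu contact kernel steepness (1/length).
#' @slot contactRc contact kernel midpoint (length).
#' @export
setClass("MiChroMParameters",
  representation(
    feneK = "numeric", feneR0 = "numeric",
    stericEpsilon = "numeric", stericSigma = "numeric",
    confinementRadius = "numeric", confinementK = "numeric",
    typeMatrix = "matrix",
    idealGamma = "numeric", dMin = "integer", dMax = "integer",
    loopChi = "numeric", contactMu = "numeric", contactRc = "numeric"
  )
)
setValidity("MiChroMParameters", function(object) {
  msg <- character()
  tm <- object@typeMatrix
  if (!is.numeric(tm) || nrow(tm) != 7L || ncol(tm) != 7L)
    msg <- c(msg, "typeMatrix must be a numeric 7x7 matrix")
  else if (!isTRUE(all.equal(tm, t(tm))))
    msg <- c(msg, "typeMatrix must be symmetric")
  if (object@feneR0 <= object@stericSigma)
    msg <- c(msg, "feneR0 must exceed stericSigma")
  if (object@dMin < 3L)
    msg <- c(msg, "dMin must be >= 3 (nearest and next-nearest neighbours are handled by the connectivity and steric terms)")
  if (object@dMax < object@dMin) msg <- c(msg, "dMax must be >= dMin")
  lens <- c(object@feneR0, object@stericSigma, object@confinementRadius,
            object@contactRc)
  if (any(lens <= 0)) msg <- c(msg, "all lengths must be positive")
  if (object@contactMu <= 0) msg <- c(msg, "contactMu must be positive")
  if (length(object@idealGamma) != 3L)
    msg <- c(msg, "idealGamma must have exactly three coefficients")
  if (length(msg)) msg else TRUE
})

## ChromosomeSystem ------------------------------------------------------------

#' A simulatable chromosome: bead types, loops and parameters
#'
#' Encodes the 1D inputs of the physical model: the per-bead chromatin
#' type sequence, the list of stable loops, the bead resolution, and the
#' energy-function parameters.
#'
#' @slot beadTypes integer vector of type indices in 0..6 (see
#'   [annotationsToBeadTypes()]).
#' @slot loops two-column integer matrix of 1-based anchor bead pairs.
#' @slot nBeads number of beads.
#' @slot resolution base pairs per bead (default 50000).
#' @slot parameters a [MiChroMParameters-class] object.
#' @seealso [chromosomeSystem()], [makeBlockCopolymer()]
#' @export
setClass("ChromosomeSystem",
  representation(beadTypes = "integer", loops = "matrix",
                 nBeads = "integer", resolution = "numeric",
                 parameters = "MiChroMParameters")
)
setValidity("ChromosomeSystem", function(object) {
  msg <- character()
  if (length(object@beadTypes) != object@nBeads)
    msg <- c(msg, "beadTypes length must equal nBeads")
  if (any(object@beadTypes < 0L | object@beadTypes > 6L))
    msg <- c(msg, "beadTypes must lie in 0..6")
  if (nrow(object@loops)) {
    if (ncol(object@loops) != 2L) msg <- c(msg, "loops must be a 2-column matrix")
    else if (any(object@loops < 1L | object@loops > object@nBeads))
      msg <- c(msg, "loop anchors must lie in 1..nBeads")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ChromosomeSystem-class
#' @param beadTypes integer type indices (0..6), one per bead.
#' @param loops optional 2-column matrix/data.frame of anchor bead pairs
#'   (1-based). Exact duplicate pairs are collapsed with a warning.
#' @param resolution base pairs per bead.
#' @param parameters a [MiChroMParameters-class]; defaults to
#'   [michromParameters()].
#' @return A [ChromosomeSystem-class] object.
#' @export
chromosomeSystem <- function(beadTypes, loops = NULL, resolution = 50000,
                             parameters = michromParameters()) {
  beadTypes <- as.integer(beadTypes)
  if (is.null(loops)) {
    loops <- matrix(integer(), ncol = 2L)
  } else {
    loops <- as.matrix(as.data.frame(loops)[, 1:2])
    storage.mode(loops) <- "integer"
    loops <- dedupLoops(loops)
  }
  dimnames(loops) <- NULL
  new("ChromosomeSystem", beadTypes = beadTypes, loops = loops,
      nBeads = length(beadTypes), resolution = as.numeric(resolution),
      parameters = parameters)
}

#' Collapse duplicate loop entries
#'
#' Unordered duplicate anchor pairs are collapsed to a single entry with a
#' warning; anchor order within a pair is canonicalised (small, large).
#'
#' @param loops 2-column integer matrix of anchor pairs.
#' @return Deduplicated 2-column integer matrix.
#' @export
dedupLoops <- function(loops) {
  if (!nrow(loops)) return(loops)
  canon <- cbind(pmin(loops[, 1L], loops[, 2L]), pmax(loops[, 1L], loops[, 2L]))
  dup <- duplicated(paste(canon[, 1L], canon[, 2L]))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate loop entr%s", sum(dup),
                    if (sum(dup) == 1L) "y" else "ies"))
    canon <- canon[!dup, , drop = FALSE]
  }
  storage.mode(canon) <- "integer"
  canon
}

## ContactMap ------------------------------------------------------------------

#' Locus-by-locus contact frequency matrix
#'
#' A symmetric non-negative matrix reporting the frequency of spatial
#' contact between pairs of loci, as measured over a structural ensemble
#' ([contactMap()]) or generated synthetically ([makeBlockContactMap()]).
#'
#' @slot matrix symmetric numeric matrix of contact frequencies.
#' @slot resolution bin size in base pairs.
#' @slot chrom chromosome label.
#' @slot nFramesUsed number of frames the map was estimated from (0 for
#'   synthetic maps).
#' @export
setClass("ContactMap",
  representation(matrix = "matrix", resolution = "numeric",
                 chrom = "character", nFramesUsed = "integer")
)
setValidity("ContactMap", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (any(!is.finite(m))) msg <- c(msg, "matrix entries must be finite")
  if (any(m < 0)) msg <- c(msg, "matrix entries must be non-negative")
  if (nrow(m) && max(abs(m - t(m))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @rdname ContactMap-class
#' @param matrix,resolution,chrom,nFramesUsed slot values.
#' @return A [ContactMap-class] object.
#' @export
newContactMap <- function(matrix, resolution = 50000, chrom = "1",
                          nFramesUsed = 0L) {
  matrix <- unname(as.matrix(matrix))
  new("ContactMap", matrix = matrix, resolution = as.numeric(resolution),
      chrom = as.character(chrom), nFramesUsed = as.integer(nFramesUsed))
}

## CompartmentProfile ----------------------------------------------------------

#' First-eigenvector compartment profile of a contact map
#'
#' The leading eigenvector of the Pearson correlation matrix of the
#' observed/expected contact map, with masked (zero/centromeric) loci
#' carried as `NA`. The sign of an eigenvector is arbitrary; the
#' orientation rule actually applied is recorded in `signConvention`.
#'
#' @slot eigenvector signed numeric, one entry per locus (`NA` = masked);
#'   unit norm over unmasked entries.
#' @slot signConvention text describing how the global sign was fixed.
#' @slot explainedShare leading eigenvalue as a fraction of the total
#'   absolute spectrum.
#' @export
setClass("CompartmentProfile",
  representation(eigenvector = "numeric", signConvention = "character",
                 explainedShare = "numeric")
)
setValidity("CompartmentProfile", function(object) {
  v <- object@eigenvector[!is.na(object@eigenvector)]
  if (length(v) && abs(sum(v^2) - 1) > 1e-6) "eigenvector must have unit norm over unmasked loci"
  else TRUE
})

## SamplerConfig ---------------------------------------------------------------

#' Langevin sampler configuration
#'
#' @slot nSteps total integration steps.
#' @slot saveEvery frame saving stride (steps).
#' @slot timestep integration timestep (reduced time).
#' @slot friction Langevin friction coefficient (reduced).
#' @slot temperature reduced temperature (default 1).
#' @slot seed RNG seed; replica k uses `seed + k - 1`.
#' @slot nReplicas number of independent replicas.
#' @slot equilibrationSteps steps discarded before the first saved frame.
#' @export
setClass("SamplerConfig",
  representation(nSteps = "integer", saveEvery = "integer",
                 timestep = "numeric", friction = "numeric",
                 temperature = "numeric", seed = "integer",
                 nReplicas = "integer", equilibrationSteps = "integer")
)
setValidity("SamplerConfig", function(object) {
  msg <- character()
  if (object@nSteps <= 0L) msg <- c(msg, "nSteps must be positive")
  if (object@saveEvery <= 0L) msg <- c(msg, "saveEvery must be positive")
  if (object@saveEvery > object@nSteps) msg <- c(msg, "saveEvery must not exceed nSteps")
  if (object@timestep <= 0) msg <- c(msg, "timestep must be positive")
  if (object@friction <= 0) msg <- c(msg, "friction must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (object@nReplicas < 1L) msg <- c(msg, "nReplicas must be >= 1")
  if (object@equilibrationSteps < 0L) msg <- c(msg, "equilibrationSteps must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname SamplerConfig-class
#' @param nSteps,saveEvery,timestep,friction,temperature,seed,nReplicas,equilibrationSteps
#'   see slots.
#' @return A [SamplerConfig-class] object.
#' @export
samplerConfig <- function(nSteps, saveEvery, seed, timestep = 0.01,
                          friction = 0.1, temperature = 1,
                          nReplicas = 1L, equilibrationSteps = 0L) {
  new("SamplerConfig", nSteps = as.integer(nSteps),
      saveEvery = as.integer(saveEvery), timestep = as.numeric(timestep),
      friction = as.numeric(friction), temperature = as.numeric(temperature),
      seed = as.integer(seed), nReplicas = as.integer(nReplicas),
      equilibrationSteps = as.integer(equilibrationSteps))
}
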