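#' @include AllClasses.R
NULL

#' Accessors for structural ensembles and contact maps
#'
#' @param x a [ChromEnsemble-class], [ContactMap-class] or
#'   [BinnedTrack-class] object, as appropriate.
#' @param model frame number (1-based) for [coords()].
#' @name accessors
NULL

#' @rdname accessors
#' @return `nModels()`: number of coordinate frames.
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname accessors
#' @export
setMethod("nModels", "ChromEnsemble", function(x) length(x@models))

#' @rdname accessors
#' @return `nRecords()`: number of nuclear elements.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @rdname accessors
#' @export
setMethod("nRecords", "ChromEnsemble", function(x) nrow(x@records))

#' @rdname accessors
#' @return `records()`: the per-element metadata `data.frame`.
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "ChromEnsemble", function(x) x@records)

#' @rdname accessors
#' @return `loops()`: the loop `data.frame` / anchor matrix.
#' @export
setGeneric("loops", function(x) standardGeneric("loops"))
#' @rdname accessors
#' @export
setMethod("loops", "ChromEnsemble", function(x) x@loops)
#' @rdname accessors
#' @export
setMethod("loops", "ChromosomeSystem", function(x) x@loops)

#' @rdname accessors
#' @return `ndbHeader()`: the header metadata list.
#' @export
setGeneric("ndbHeader", function(x) standardGeneric("ndbHeader"))
#' @rdname accessors
#' @export
setMethod("ndbHeader", "ChromEnsemble", function(x) x@header)

#' @rdname accessors
#' @return `coords()`: the n-by-3 coordinate matrix of one frame.
#' @export
setGeneric("coords", function(x, model = 1L) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "ChromEnsemble", function(x, model = 1L) {
  stopifnot(model >= 1L, model <= length(x@models))
  x@models[[model]]
})

#' @rdname accessors
#' @return `contactMatrix()`: the symmetric frequency matrix.
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))
#' @rdname accessors
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@matrix)

#' @rdname accessors
#' @return `trackValues()`: per-bin signal values.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setMethod("trackValues", "BinnedTrack", function(x) x@values)

#' @rdname accessors
#' @return `annotationLabels()`: per-bin annotation labels.
#' @export
setGeneric("annotationLabels", function(x) standardGeneric("annotationLabels"))
#' @rdname accessors
#' @export
setMethod("annotationLabels", "AnnotationSequence", function(x) x@labels)

#' @rdname accessors
#' @return `eigenvector()`: signed per-locus compartment eigenvector.
#' @export
setGeneric("eigenvector", function(x) standardGeneric("eigenvector"))
#' @rdname accessors
#' @export
setMethod("eigenvector", "CompartmentProfile", function(x) x@eigenvector)

#' @rdname accessors
#' @return `beadTypes()`: integer per-bead type indices.
#' @export
setGeneric("beadTypes", function(x) standardGeneric("beadTypes"))
#' @rdname accessors
#' @export
setMethod("beadTypes", "ChromosomeSystem", function(x) x@beadTypes)

#' @rdname accessors
#' @return `modelParameters()`: the [MiChroMParameters-class] of a system.
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))
#' @rdname accessors
#' @export
setMethod("modelParameters", "ChromosomeSystem", function(x) x@parameters)

## show methods ---------------------------------------------------------------

setMethod("show", "ChromEnsemble", function(object) {
  rec <- object@records
  cat(sprintf("ChromEnsemble: %d element%s, %d model%s%s\n",
              nrow(rec), if (nrow(rec) == 1) "" else "s",
              length(object@models), if (length(object@models) == 1) "" else "s",
              if (object@isTimeSeries) " (time series)" else ""))
  cat(sprintf("  chains: %s\n", paste(unique(rec$chain_id), collapse = ", ")))
  cat(sprintf("  CHROM beads: %d  DNAELE: %d  loops: %d\n",
              sum(rec$element_type == "CHROM"),
              sum(rec$element_type == "DNAELE"), nrow(object@loops)))
  cat(sprintf("  length unit: %s\n", object@header$length_unit))
})

setMethod("show", "BinnedTrack", function(object) {
  cat(sprintf("BinnedTrack %s on chr %s: %d bins @ %g bp\n",
              object@mark, object@chrom, length(object@values),
              object@resolution))
  cat(sprintf("  total signal %.4g, max %.4g\n",
              sum(object@values), if (length(object@values)) max(object@values) else 0))
})

setMethod("show", "AnnotationSequence", function(object) {
  tab <- table(factor(object@labels, levels = annotationAlphabet()))
  cat(sprintf("AnnotationSequence on chr %s: %d loci @ %g bp\n",
              object@chrom, length(object@labels), object@resolution))
  cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = "  "), "\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap chr %s: %d x %d loci @ %g bp (%d frame%s)\n",
              object@chrom, nrow(object@matrix), ncol(object@matrix),
              object@resolution, object@nFramesUsed,
              if (object@nFramesUsed == 1) "" else "s"))
})

setMethod("show", "ChromosomeSystem", function(object) {
  cat(sprintf("ChromosomeSystem: %d beads @ %g bp, %d loop%s\n",
              object@nBeads, object@resolution, nrow(object@loops),
              if (nrow(object@loops) == 1) "" else "s"))
  tab <- table(object@beadTypes)
  cat("  bead types:", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                             collapse = "  "), "\n")
})

setMethod("show", "MiChroMParameters", function(object) {
  cat("MiChroMParameters (reduced units)\n")
  cat(sprintf("  FENE k=%g r0=%g | steric eps=%g sigma=%g\n",
              object@feneK, object@feneR0, object@stericEpsilon,
              object@stericSigma))
  cat(sprintf("  confinement R=%g k=%g | kernel mu=%g rc=%g\n",
              object@confinementRadius, object@confinementK,
              object@contactMu, object@contactRc))
  cat(sprintf("  ideal gamma=(%s) d in [%d, %d] | loop chi=%g\n",
              paste(signif(object@idealGamma, 4), collapse = ", "),
              object@dMin, object@dMax, object@loopChi))
})

setMethod("show", "CompartmentProfile", function(object) {
  v <- object@eigenvector
  cat(sprintf("CompartmentProfile: %d loci (%d masked), explained share %.3f\n",
              length(v), sum(is.na(v)), object@explainedShare))
  cat(sprintf("  sign convention: %s\n", object@signConvention))
})

setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf(
    "SamplerConfig: %d steps (equil %d), save every %d, dt=%g, friction=%g, T=%g, seed=%d, replicas=%d\n",
    object@nSteps, object@equilibrationSteps, object@saveEvery,
    object@timestep, object@friction, object@temperature, object@seed,
    object@nReplicas))
})
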