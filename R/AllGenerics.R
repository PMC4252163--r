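#' @rdname MethylIntensitySet-accessors
#' @export
setGeneric("methylated", function(x) standardGeneric("methylated"))
#' @rdname MethylIntensitySet-accessors
#' @export
setGeneric("unmethylated", function(x) standardGeneric("unmethylated"))
#' @rdname MethylIntensitySet-accessors
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))
#' @rdname MethylIntensitySet-accessors
#' @export
setGeneric("beadCount", function(x) standardGeneric("beadCount"))
#' @rdname MethylIntensitySet-accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname MethylIntensitySet-accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname PairedDesign-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname PairedDesign-accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @rdname PairedDesign-accessors
#' @export
setGeneric("affectedSamples", function(x) standardGeneric("affectedSamples"))
#' @rdname PairedDesign-accessors
#' @export
setGeneric("unaffectedSamples", function(x) standardGeneric("unaffectedSamples"))

#' Accessors for MethylIntensitySet
#'
#' `methylated()`, `unmethylated()`, `detectionP()` and `beadCount()` return
#' the corresponding assay matrix; `manifest()` and `sampleSheet()`
#' reassemble the probe manifest / sample sheet as plain `data.frame`s.
#'
#' @param x a [MethylIntensitySet-class].
#' @name MethylIntensitySet-accessors
NULL

#' @rdname MethylIntensitySet-accessors
setMethod("methylated", "MethylIntensitySet",
          function(x) assay(x, "M"))
#' @rdname MethylIntensitySet-accessors
setMethod("unmethylated", "MethylIntensitySet",
          function(x) assay(x, "U"))
#' @rdname MethylIntensitySet-accessors
setMethod("detectionP", "MethylIntensitySet",
          function(x) assay(x, "detectionP"))
#' @rdname MethylIntensitySet-accessors
setMethod("beadCount", "MethylIntensitySet",
          function(x) assay(x, "beadCount"))
#' @rdname MethylIntensitySet-accessors
setMethod("manifest", "MethylIntensitySet", function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(data.frame(probe_id = rownames(x)), rd)[, manifestColumns]
})
#' @rdname MethylIntensitySet-accessors
setMethod("sampleSheet", "MethylIntensitySet", function(x) {
  cd <- as.data.frame(colData(x))
  cbind(data.frame(sample_id = colnames(x)), cd)
})

setMethod("show", "MethylIntensitySet", function(object) {
  rd <- rowData(object)
  cat("MethylIntensitySet:", nrow(object), "probes x", ncol(object),
      "samples\n")
  cat("  design types:",
      paste(names(table(rd$design_type)), table(rd$design_type),
            collapse = ", "), "\n")
  cat("  SNP-control probes:", sum(rd$is_snp_control), "\n")
  cat("  assays: M, U, detectionP, beadCount\n")
})

#' Accessors for PairedDesign
#'
#' @param x a [PairedDesign-class].
#' @name PairedDesign-accessors
NULL

#' @rdname PairedDesign-accessors
setMethod("nPairs", "PairedDesign", function(x) nrow(x@pairs))
#' @rdname PairedDesign-accessors
setMethod("pairIds", "PairedDesign", function(x) x@pairs$pair_id)
#' @rdname PairedDesign-accessors
setMethod("affectedSamples", "PairedDesign", function(x) x@pairs$affected)
#' @rdname PairedDesign-accessors
setMethod("unaffectedSamples", "PairedDesign", function(x) x@pairs$unaffected)

setMethod("show", "PairedDesign", function(object) {
  cat("PairedDesign with", nPairs(object), "twin pairs\n")
  print(utils::head(object@pairs, 5))
  if (nPairs(object) > 5) cat("  ...\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat("  samples removed:", nrow(object@samplesRemoved),
      " retained:", object@nSamplesRetained, "\n")
  cat("  probes removed: ", nrow(object@probesRemoved),
      " retained:", object@nProbesRetained, "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPairs, "pairs,", object@nProbes, "probes (",
      object@nSnpProbes, "SNP controls ), seed", object@seed, "\n")
  cat("  planted DMPs:", object@dmpSetSize, "at delta", object@delta, "\n")
  cat("  variance inflation lambda", object@varInflationLambda, "on",
      sprintf("%.0f%%", 100 * object@fracVarInflated), "of probes\n")
})
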