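#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

manifestColumns <- c("probe_id", "chrom", "pos", "design_type",
                     "is_snp_control", "strand")

#' Container for Infinium-style intensity data
#'
#' `MethylIntensitySet` extends
#' [SummarizedExperiment::SummarizedExperiment] with four mandatory assays:
#' `M` (methylated intensities), `U` (unmethylated intensities),
#' `detectionP` (per-probe, per-sample detection p-values) and `beadCount`
#' (number of beads averaged per measurement). Probe metadata (chromosome,
#' 1-based position, Infinium design type I/II, SNP-control flag, strand)
#' lives in `rowData`; the sample sheet (pair id, affected status, sex,
#' batch) lives in `colData`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("MethylIntensitySet", contains = "SummarizedExperiment")

setValidity("MethylIntensitySet", function(object) {
  msg <- character()
  need <- c("M", "U", "detectionP", "beadCount")
  have <- names(assays(object))
  if (!all(need %in% have))
    msg <- c(msg, paste0("missing assay(s): ",
                         paste(setdiff(need, have), collapse = ", ")))
  else {
    if (any(assay(object, "M") < 0) || any(assay(object, "U") < 0))
      msg <- c(msg, "negative intensities")
    dp <- assay(object, "detectionP")
    if (any(dp < 0 | dp > 1))
      msg <- c(msg, "detection p-values outside [0, 1]")
    if (any(assay(object, "beadCount") < 1))
      msg <- c(msg, "bead counts below 1")
  }
  rd <- rowData(object)
  needRd <- c("chrom", "pos", "design_type", "is_snp_control", "strand")
  if (!all(needRd %in% colnames(rd)))
    msg <- c(msg, "rowData must carry chrom, pos, design_type, is_snp_control, strand")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylIntensitySet
#'
#' @param M,U,detectionP,beadCount numeric matrices (probes x samples) with
#'   identical dimnames.
#' @param manifest a probe manifest `data.frame` as returned by
#'   [readManifest()]; must cover every row of `M`.
#' @param sampleSheet a sample sheet `data.frame` as returned by
#'   [readSampleSheet()]; must cover every column of `M`.
#' @return a validated [MethylIntensitySet-class] object.
#' @export
MethylIntensitySet <- function(M, U, detectionP, beadCount, manifest,
                               sampleSheet) {
  stopIfNot(!is.null(rownames(M)) && !is.null(colnames(M)),
            "intensity matrices need probe rownames and sample colnames")
  manifest <- validateManifest(manifest)
  sampleSheet <- validateSampleSheet(sampleSheet)
  missingProbes <- setdiff(rownames(M), manifest$probe_id)
  stopIfNot(length(missingProbes) == 0, "probes absent from manifest: ",
            paste(utils::head(missingProbes, 3), collapse = ", "))
  missingSamples <- setdiff(colnames(M), sampleSheet$sample_id)
  stopIfNot(length(missingSamples) == 0, "samples absent from sample sheet: ",
            paste(utils::head(missingSamples, 3), collapse = ", "))
  rd <- manifest[match(rownames(M), manifest$probe_id), ]
  rownames(rd) <- rd$probe_id
  cd <- sampleSheet[match(colnames(M), sampleSheet$sample_id), ]
  rownames(cd) <- cd$sample_id
  se <- SummarizedExperiment(
    assays = list(M = M, U = U, detectionP = detectionP,
                  beadCount = beadCount),
    rowData = DataFrame(rd[setdiff(colnames(rd), "probe_id")]),
    colData = DataFrame(cd[setdiff(colnames(cd), "sample_id")]))
  new("MethylIntensitySet", se)
}

#' Twin-pair design: which sample is the affected twin in each pair
#'
#' @slot pairs a `data.frame` with columns `pair_id`, `affected`,
#'   `unaffected`, ordered lexicographically by `pair_id`.
#' @export
setClass("PairedDesign", representation(pairs = "data.frame"))

setValidity("PairedDesign", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("pair_id", "affected", "unaffected") %in% colnames(p)))
    msg <- c(msg, "pairs needs columns pair_id, affected, unaffected")
  else {
    ids <- c(p$affected, p$unaffected)
    if (anyDuplicated(ids)) msg <- c(msg, "a sample id appears more than once")
    if (anyDuplicated(p$pair_id)) msg <- c(msg, "duplicated pair_id")
    if (is.unsorted(p$pair_id)) msg <- c(msg, "pairs must be sorted by pair_id")
  }
  if (length(msg)) msg else TRUE
})

#' Per-stage quality-control report
#'
#' Records which samples/probes a QC filter removed and why, and the counts
#' retained afterwards.
#'
#' @slot samplesRemoved,probesRemoved `data.frame`s with columns `id`, `reason`.
#' @slot nSamplesRetained,nProbesRetained integer counts after filtering.
#' @export
setClass("QCReport",
         representation(samplesRemoved = "data.frame",
                        probesRemoved = "data.frame",
                        nSamplesRetained = "integer",
                        nProbesRetained = "integer"))

QCReport <- function(samplesRemoved = emptyRemoval(),
                     probesRemoved = emptyRemoval(),
                     nSamplesRetained, nProbesRetained) {
  new("QCReport", samplesRemoved = samplesRemoved,
      probesRemoved = probesRemoved,
      nSamplesRetained = as.integer(nSamplesRetained),
      nProbesRetained = as.integer(nProbesRetained))
}

emptyRemoval <- function()
  data.frame(id = character(), reason = character())

#' Synthetic twin-pair dataset configuration
#'
#' Holds every parameter of the generative model used by
#' [simulateDataset()] and [simulatePhenotypes()]; see those functions for
#' the model itself. Construct with [simConfig()], which supplies defaults
#' emulating an 18-pair 450K-style discordant-twin study.
#'
#' @export
setClass("SimConfig", representation(
  nPairs = "integer", nProbes = "integer", nSnpProbes = "integer",
  fracTypeII = "numeric", seed = "integer",
  mixtureWeights = "numeric", mixtureShape1 = "numeric",
  mixtureShape2 = "numeric",
  tau = "numeric", sigma = "numeric",
  dmpSetSize = "integer", delta = "numeric",
  varInflationLambda = "numeric", fracVarInflated = "numeric",
  totalIntensityLogMean = "numeric", totalIntensityLogSd = "numeric",
  typeIOffset = "numeric",
  detectionFailRate = "numeric", beadcountMean = "numeric",
  mzMode = "logical", snpNoiseSd = "numeric", phenoSd = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  prop <- c(fracTypeII = object@fracTypeII,
            fracVarInflated = object@fracVarInflated,
            detectionFailRate = object@detectionFailRate)
  bad <- prop < 0 | prop > 1
  if (any(bad))
    msg <- c(msg, paste0("proportions outside [0,1]: ",
                         paste(names(prop)[bad], collapse = ", ")))
  if (abs(object@delta) >= 1) msg <- c(msg, "delta must lie in (-1, 1)")
  if (object@varInflationLambda < 1)
    msg <- c(msg, "varInflationLambda must be >= 1")
  if (object@dmpSetSize > object@nProbes - object@nSnpProbes)
    msg <- c(msg, "dmpSetSize exceeds number of non-SNP probes")
  if (length(object@mixtureWeights) != 3 ||
      abs(sum(object@mixtureWeights) - 1) > 1e-8)
    msg <- c(msg, "mixtureWeights must be 3 weights summing to 1")
  if (object@seed < 0 || object@seed > 2^31 - 1000)
    msg <- c(msg, "seed out of range")
  if (length(msg)) msg else TRUE
})
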