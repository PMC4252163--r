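# Tabular input/output. All tables are tab-separated UTF-8 with a header
# row; lines starting with '#' are ignored on input.

readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

validateManifest <- function(m) {
  stopIfNot(all(manifestColumns %in% colnames(m)),
            "manifest needs columns: ", paste(manifestColumns, collapse = ", "))
  m <- m[, manifestColumns]
  dup <- m$probe_id[duplicated(m$probe_id)]
  stopIfNot(length(dup) == 0,
            "duplicated probe_id in manifest: ", paste(unique(dup), collapse = ", "))
  stopIfNot(all(m$pos >= 1), "manifest positions must be >= 1 (1-based); ",
            "offending probe(s): ",
            paste(utils::head(m$probe_id[m$pos < 1], 3), collapse = ", "))
  m$is_snp_control <- as.logical(m$is_snp_control)
  stopIfNot(!any(is.na(m$is_snp_control)), "is_snp_control must be logical")
  badType <- !m$is_snp_control & !m$design_type %in% c("I", "II")
  stopIfNot(!any(badType),
            "design_type must be I or II for every non-SNP-control probe")
  stopIfNot(all(m$strand %in% c("+", "-", ".")), "strand must be +, - or .")
  m <- m[order(m$chrom, m$pos, m$probe_id), ]
  rownames(m) <- NULL
  m
}

#' Read a probe manifest
#'
#' Reads a tab-separated probe manifest with columns `probe_id`, `chrom`,
#' `pos` (1-based), `design_type` (`I`/`II`), `is_snp_control`
#' (logical) and `strand` (`+`/`-`/`.`). Rows are returned sorted by
#' `(chrom, pos)`. SNP-control probes are identity/zygosity controls and are
#' excluded from all DMP, variance and region statistics downstream.
#'
#' @param path path to a TSV file.
#' @return a validated manifest `data.frame`.
#' @export
readManifest <- function(path) validateManifest(readTsv(path))

#' @rdname readManifest
#' @param m a manifest `data.frame`.
#' @export
writeManifest <- function(m, path) writeTsv(validateManifest(m), path)

validateSampleSheet <- function(s) {
  need <- c("sample_id", "pair_id", "status", "sex")
  stopIfNot(all(need %in% colnames(s)),
            "sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!"batch" %in% colnames(s)) s$batch <- s$pair_id
  stopIfNot(!anyDuplicated(s$sample_id), "duplicated sample_id")
  stopIfNot(all(s$status %in% c("affected", "unaffected")),
            "status must be 'affected' or 'unaffected'")
  stopIfNot(all(s$sex %in% c("M", "F")), "sex must be 'M' or 'F'")
  for (pid in unique(s$pair_id)) {
    rows <- s[s$pair_id == pid, ]
    stopIfNot(nrow(rows) == 2, "pair ", pid, " must have exactly two samples")
    stopIfNot(sum(rows$status == "affected") == 1,
              "pair ", pid, " must have exactly one affected member")
    stopIfNot(length(unique(rows$sex)) == 1,
              "pair ", pid, ": MZ twins must share sex")
    stopIfNot(length(unique(rows$batch)) == 1,
              "pair ", pid, ": twins must share a batch/array")
  }
  s
}

#' Read / write a sample sheet
#'
#' Tab-separated sample sheet with columns `sample_id`, `pair_id`, `status`
#' (`affected`/`unaffected`), `sex` (`M`/`F`) and optionally `batch`. Each
#' pair must consist of exactly one affected and one unaffected member
#' sharing sex (MZ twins) and batch (twins co-processed on one array).
#'
#' @param path path to a TSV file.
#' @return a validated sample-sheet `data.frame`.
#' @export
readSampleSheet <- function(path) validateSampleSheet(readTsv(path))

#' @rdname readSampleSheet
#' @param s a sample-sheet `data.frame`.
#' @export
writeSampleSheet <- function(s, path) writeTsv(validateSampleSheet(s), path)

#' Build the paired design from a sample sheet
#'
#' Pairs are ordered lexicographically by `pair_id`, so the design is
#' invariant to the row order of the sheet.
#'
#' @param sheet a sample sheet `data.frame` (see [readSampleSheet()]).
#' @return a [PairedDesign-class].
#' @export
buildDesign <- function(sheet) {
  sheet <- validateSampleSheet(sheet)
  pids <- sort(unique(sheet$pair_id))
  pairs <- data.frame(
    pair_id = pids,
    affected = vapply(pids, function(p)
      sheet$sample_id[sheet$pair_id == p & sheet$status == "affected"], ""),
    unaffected = vapply(pids, function(p)
      sheet$sample_id[sheet$pair_id == p & sheet$status == "unaffected"], ""))
  rownames(pairs) <- NULL
  new("PairedDesign", pairs = pairs)
}

#' Read / write a longitudinal phenotype table
#'
#' Rows of `(pair_id, wave, score_twin_a, score_twin_b)` holding SMFQ
#' depression-symptom scores (0-26 scale) for both twins at each
#' measurement wave.
#'
#' @param path path to a TSV file.
#' @return a `data.frame`.
#' @export
readPhenotypeTable <- function(path) {
  p <- readTsv(path)
  need <- c("pair_id", "wave", "score_twin_a", "score_twin_b")
  stopIfNot(all(need %in% colnames(p)),
            "phenotype table needs columns: ", paste(need, collapse = ", "))
  sc <- c(p$score_twin_a, p$score_twin_b)
  stopIfNot(all(sc >= 0 & sc <= 26), "SMFQ scores must lie in [0, 26]")
  p
}

#' @rdname readPhenotypeTable
#' @param p a phenotype `data.frame`.
#' @export
writePhenotypeTable <- function(p, path) writeTsv(p, path)

#' Select phenotype-discordant twin pairs
#'
#' A pair qualifies when the within-pair score difference reaches
#' `threshold` (inclusively) on at least `minWaves` waves, with the *same*
#' twin scoring higher on every qualifying wave (consistent discordancy).
#' Qualifying waves need not be consecutive.
#'
#' @param pheno phenotype table (see [readPhenotypeTable()]).
#' @param threshold minimum absolute score difference; the default 6 is
#'   roughly 1.5 SD of within-pair SMFQ differences in adolescent cohorts.
#' @param minWaves minimum number of qualifying waves (default 2).
#' @return a sorted character vector of selected `pair_id`s; attribute
#'   `higherScorer` records which twin (`"a"`/`"b"`) scored higher.
#' @export
selectDiscordantPairs <- function(pheno, threshold = 6, minWaves = 2) {
  stopIfNot(threshold > 0, "threshold must be positive")
  stopIfNot(minWaves >= 1, "minWaves must be >= 1")
  if (nrow(pheno) == 0)
    return(structure(character(),
                     higherScorer = stats::setNames(character(), character())))
  sel <- character(); who <- character()
  for (pid in sort(unique(pheno$pair_id))) {
    d <- pheno$score_twin_a[pheno$pair_id == pid] -
      pheno$score_twin_b[pheno$pair_id == pid]
    qual <- d[abs(d) >= threshold]
    if (length(qual) >= minWaves && length(unique(sign(qual))) == 1) {
      sel <- c(sel, pid)
      who <- c(who, if (qual[1] > 0) "a" else "b")
    }
  }
  structure(sel, higherScorer = stats::setNames(who, sel))
}

# ---- intensity matrices ----------------------------------------------------

#' Read / write probes-x-samples matrices as TSV
#'
#' First column `probe_id` becomes rownames; remaining columns are samples.
#'
#' @param path path to a TSV file.
#' @return a numeric matrix with probe rownames and sample colnames.
#' @export
readMatrixTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname readMatrixTsv
#' @param m a matrix with dimnames.
#' @export
writeMatrixTsv <- function(m, path) {
  writeTsv(cbind(data.frame(probe_id = rownames(m)), as.data.frame(m)), path)
}

#' Read / write a full intensity set
#'
#' `readIntensityTables()` assembles a [MethylIntensitySet-class] from four
#' matrix TSVs plus manifest and sample sheet; `writeIntensityTables()`
#' writes the six files under `dir` with a common `prefix`.
#'
#' @param dir directory holding/receiving the tables.
#' @param prefix file-name prefix (default `"data"`).
#' @return a [MethylIntensitySet-class].
#' @export
readIntensityTables <- function(dir, prefix = "data") {
  f <- function(x) file.path(dir, paste0(prefix, "_", x, ".tsv"))
  MethylIntensitySet(
    M = readMatrixTsv(f("methylated")),
    U = readMatrixTsv(f("unmethylated")),
    detectionP = readMatrixTsv(f("detection_p")),
    beadCount = readMatrixTsv(f("beadcount")),
    manifest = readManifest(f("manifest")),
    sampleSheet = readSampleSheet(f("samples")))
}

#' @rdname readIntensityTables
#' @param x a [MethylIntensitySet-class].
#' @export
writeIntensityTables <- function(x, dir, prefix = "data") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- function(nm) file.path(dir, paste0(prefix, "_", nm, ".tsv"))
  writeMatrixTsv(methylated(x), f("methylated"))
  writeMatrixTsv(unmethylated(x), f("unmethylated"))
  writeMatrixTsv(detectionP(x), f("detection_p"))
  writeMatrixTsv(beadCount(x), f("beadcount"))
  writeManifest(manifest(x), f("manifest"))
  writeSampleSheet(sampleSheet(x), f("samples"))
  invisible(dir)
}

# ---- genomic interchange ---------------------------------------------------

#' Convert a manifest to GRanges / export as BED
#'
#' The manifest's 1-based probe coordinate `pos` maps to the 0-based
#' half-open BED interval `[pos - 1, pos)`; the conversion happens inside
#' GenomicRanges/rtracklayer and nowhere else in the package.
#'
#' @param m a manifest `data.frame`.
#' @return `manifestToGRanges()`: a [GenomicRanges::GRanges] with probe ids
#'   as names; `exportManifestBed()`: the output path, invisibly.
#' @export
manifestToGRanges <- function(m) {
  m <- validateManifest(m)
  gr <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    ranges = IRanges::IRanges(start = m$pos, width = 1),
    strand = ifelse(m$strand == ".", "*", m$strand))
  names(gr) <- m$probe_id
  gr$name <- m$probe_id
  gr
}

#' @rdname manifestToGRanges
#' @param path output BED path.
#' @export
exportManifestBed <- function(m, path) {
  rtracklayer::export(manifestToGRanges(m), path, format = "BED")
  invisible(path)
}

#' Read a TSS annotation BED file
#'
#' Expects BED6 (chrom, start, end, gene symbol, score, strand); each
#' interval's start is taken as the transcription start site coordinate.
#' Malformed lines are reported with their line number.
#'
#' @param path path to a BED file.
#' @return a [GenomicRanges::GRanges] with metadata column `name` (gene
#'   symbol) and strand set.
#' @export
readTssBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nf < 6)) {
    bad <- which(keep)[which(nf < 6)[1]]
    stop("malformed BED line ", bad, " in ", path,
         ": expected >= 6 tab-separated fields", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  stopIfNot(all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")),
            "TSS BED entries must carry strand + or -")
  gr
}
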