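#' Gap-based differentially methylated region calling
#'
#' A deliberately transparent region caller: per chromosome, non-SNP
#' probes are sorted by position and consecutive probes at most `maxGap`
#' bp apart are greedily chained; chains with at least `minProbes` probes
#' become candidate regions. Each region's significance is a paired t-test
#' on per-pair means of the member probes' betas; Benjamini-Hochberg q
#' values are computed across regions (the uncorrected p is reported
#' alongside). This replaces index-based region schemes that depend on
#' proprietary array annotation.
#'
#' @param betas beta matrix (probes x samples).
#' @param design a [PairedDesign-class].
#' @param man probe manifest covering the probes in `betas`.
#' @param maxGap maximum within-region gap between consecutive probes, bp
#'   (default 500).
#' @param minProbes minimum probes per region (default 3).
#' @return a `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive span of member probes), `n_probes`, `probe_ids`
#'   (comma-separated), `mean_delta_beta`, `p_value`, `q_value`, ordered
#'   by `p_value`. Zero rows when nothing clusters.
#' @export
callRegions <- function(betas, design, man, maxGap = 500, minProbes = 3) {
  man <- validateManifest(man)
  man <- man[!man$is_snp_control & man$probe_id %in% rownames(betas), ]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer(),
                      probe_ids = character(), mean_delta_beta = numeric(),
                      p_value = numeric(), q_value = numeric())
  if (nrow(man) == 0) return(empty)
  aff <- affectedSamples(design); unaff <- unaffectedSamples(design)
  rows <- list()
  for (ch in unique(man$chrom)) {
    sub <- man[man$chrom == ch, ]           # already position-sorted
    grp <- cumsum(c(1, diff(sub$pos) > maxGap))
    for (g in unique(grp)) {
      member <- sub[grp == g, ]
      if (nrow(member) < minProbes) next
      regBeta <- colMeans(betas[member$probe_id, , drop = FALSE])
      d <- regBeta[aff] - regBeta[unaff]
      n <- length(d); m <- mean(d); s <- stats::sd(d)
      p <- if (s == 0) (if (m == 0) 1 else .Machine$double.xmin)
      else 2 * stats::pt(-abs(m / (s / sqrt(n))), n - 1)
      db <- rowMeans(betas[member$probe_id, aff, drop = FALSE] -
                       betas[member$probe_id, unaff, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = min(member$pos), end = max(member$pos),
        n_probes = nrow(member),
        probe_ids = paste(member$probe_id, collapse = ","),
        mean_delta_beta = mean(db), p_value = p)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Nearest-TSS gene annotation of probes
#'
#' For each probe, reports up to `maxGenes` nearest transcription start
#' sites within `window` bp, with a signed distance oriented along the
#' gene: `distance = (probe_pos - TSS_pos)` for `+`-strand genes and
#' `(TSS_pos - probe_pos)` for `-`-strand genes, so positive means the
#' probe lies downstream of the TSS in the gene's reading direction. Ties
#' in |distance| are broken by gene symbol.
#'
#' @param probes probe ids to annotate.
#' @param man probe manifest.
#' @param tss a [GenomicRanges::GRanges] of TSSs (see [readTssBed()]) or a
#'   path to a BED6 file.
#' @param window maximum |distance| in bp (default 250000).
#' @param maxGenes maximum genes per probe (default 2).
#' @return a `data.frame` with columns `probe_id`, `gene_symbol`,
#'   `distance`, `nearest_rank`; probes with no TSS in the window are
#'   absent from the output.
#' @export
annotateProbes <- function(probes, man, tss, window = 250000, maxGenes = 2) {
  if (is.character(tss)) tss <- readTssBed(tss)
  man <- validateManifest(man)
  idx <- match(probes, man$probe_id)
  stopIfNot(!anyNA(idx), "probes missing from manifest: ",
            paste(utils::head(probes[is.na(idx)], 3), collapse = ", "))
  tssChrom <- as.character(GenomicRanges::seqnames(tss))
  tssPos <- GenomicRanges::start(tss)
  tssStrand <- as.character(GenomicRanges::strand(tss))
  tssGene <- tss$name
  rows <- lapply(seq_along(probes), function(k) {
    i <- idx[k]
    on <- tssChrom == man$chrom[i]
    if (!any(on)) return(NULL)
    signedDist <- (man$pos[i] - tssPos[on]) * ifelse(tssStrand[on] == "+", 1, -1)
    keep <- abs(signedDist) <= window
    if (!any(keep)) return(NULL)
    ord <- order(abs(signedDist[keep]), tssGene[on][keep])
    take <- utils::head(ord, maxGenes)
    data.frame(probe_id = probes[k],
               gene_symbol = tssGene[on][keep][take],
               distance = signedDist[keep][take],
               nearest_rank = seq_along(take))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probe_id = character(), gene_symbol = character(),
                      distance = numeric(), nearest_rank = integer())
  rownames(out) <- NULL
  out
}
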