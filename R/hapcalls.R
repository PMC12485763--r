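## Haplotype-resolved ASM-region discovery with exclusion filters, and
## block-level ASM / epimutation calls with the coverage and effect-size
## rules used throughout the package (adjusted CpG coverage >= 5,
## >= 4 covered CpGs, |diff| > 0.4 for ASM, |diff| > 0.3 for
## epimutations, BH FDR < 0.05).

#' Haplotype DMRs (ASM regions) within one sample
#'
#' Applies the stand-in DMR caller ([callDMRs()]) between the two
#' haplotypes of a haplotype-resolved track, with the ASM effect-size
#' rule (|difference| > 0.4, FDR 0.05).
#'
#' @param track a [MethTrack-class] with `hap1` and `hap2` records.
#' @param minDiff minimum |methylation difference| (default 0.4).
#' @param ... passed to [callDMRs()].
#' @return data.frame of ASM regions (`diff` = hap1 − hap2).
#' @export
hapDMRs <- function(track, minDiff = 0.4, ...) {
  h1 <- hapTrack(track, "hap1"); h2 <- hapTrack(track, "hap2")
  if (!length(h1) || !length(h2))
    stop("track lacks haplotype-resolved records")
  t1 <- MethTrack(sampleId(track), as.character(seqnames(cpgRanges(h1))),
                  start(cpgRanges(h1)), methCounts(h1), unmethCounts(h1))
  t2 <- MethTrack(sampleId(track), as.character(seqnames(cpgRanges(h2))),
                  start(cpgRanges(h2)), methCounts(h2), unmethCounts(h2))
  callDMRs(t1, t2, minDiff = minDiff, ...)
}

#' Top-percentile SNP-density windows
#'
#' Tiles each chromosome into non-overlapping windows and returns the
#' windows whose SNP count is strictly greater than the
#' `1 - topFraction` empirical quantile of all window counts. With a
#' flat density (all windows equal) nothing is masked.
#'
#' @param snps [GenomicRanges::GRanges] of SNP positions.
#' @param genome named integer vector of chromosome lengths.
#' @param window window size in bases (default 10000).
#' @param topFraction density percentile to mask (default 0.01, the top
#'   1 percent).
#' @return [GenomicRanges::GRanges] of masked windows with metadata
#'   column `n_snps`.
#' @export
highSnpDensityWindows <- function(snps, genome, window = 10000L,
                                  topFraction = 0.01) {
  stopifnot(window > 0L, length(genome) >= 1L, !is.null(names(genome)))
  tiles <- GenomicRanges::tileGenome(genome, tilewidth = window,
                                     cut.last.tile.in.chrom = TRUE)
  cnt <- countOverlaps(tiles, snps)
  thr <- quantile(cnt, 1 - topFraction, names = FALSE, type = 7)
  masked <- tiles[cnt > thr]
  mcols(masked)$n_snps <- cnt[cnt > thr]
  masked
}

#' Exclusion filter for ASM regions
#'
#' A region is excluded iff it (a) lies on a sex chromosome, (b)
#' overlaps a known imprinted interval, (c) has a structural-variant
#' breakpoint within `svDistance` bases, or (d) overlaps a SNP-dense
#' window. Reasons are reported in that precedence order.
#'
#' @param regions [GenomicRanges::GRanges].
#' @param imprinted [GenomicRanges::GRanges] of imprinted regions.
#' @param svBreakpoints [GenomicRanges::GRanges] of SV breakpoint
#'   positions.
#' @param snpDenseWindows [GenomicRanges::GRanges], e.g. from
#'   [highSnpDensityWindows()].
#' @param sexChroms chromosome names treated as sex chromosomes.
#' @param svDistance exclusion distance around SV breakpoints, bases
#'   (default 1000).
#' @return list with `retained` (`GRanges`) and `excluded` (data.frame
#'   of coordinates plus `reason` in
#'   `{sex_chrom, imprinted, sv_proximity, snp_dense}`).
#' @export
asmRegionFilter <- function(regions, imprinted = GRanges(),
                            svBreakpoints = GRanges(),
                            snpDenseWindows = GRanges(),
                            sexChroms = c("chrX", "chrY", "X", "Y"),
                            svDistance = 1000L) {
  reason <- rep(NA_character_, length(regions))
  isSex <- as.character(seqnames(regions)) %in% sexChroms
  reason[isSex] <- "sex_chrom"
  if (length(imprinted)) {
    hit <- overlapsAny(regions, imprinted)
    reason[is.na(reason) & hit] <- "imprinted"
  }
  if (length(svBreakpoints)) {
    near <- overlapsAny(regions, svBreakpoints, maxgap = svDistance)
    reason[is.na(reason) & near] <- "sv_proximity"
  }
  if (length(snpDenseWindows)) {
    dense <- overlapsAny(regions, snpDenseWindows)
    reason[is.na(reason) & dense] <- "snp_dense"
  }
  drop <- !is.na(reason)
  excluded <- data.frame(chrom = as.character(seqnames(regions))[drop],
                         start = start(regions)[drop],
                         end = end(regions)[drop],
                         reason = reason[drop])
  list(retained = regions[!drop], excluded = excluded)
}

## per-block haplotype count sums + covered-CpG counts for one track
.blockHapCounts <- function(track, blocks, haplotype) {
  agg <- aggregateIntervals(track, blocks, haplotype = haplotype)
  agg[, c("n_cpgs", "meth_sum", "total_sum", "weighted_mean")]
}

## haplotype-combined view: explicit combined records when present,
## otherwise the hap1+hap2 sum
.combinedView <- function(track) {
  if (any(haplotypes(track) == "combined"))
    return(hapTrack(track, "combined"))
  asCombined <- function(h) {
    g <- cpgRanges(h)
    MethTrack(sampleId(track), as.character(seqnames(g)), start(g),
              methCounts(h), unmethCounts(h))
  }
  poolTracks(list(asCombined(hapTrack(track, "hap1")),
                  asCombined(hapTrack(track, "hap2"))),
             sampleId = sampleId(track))
}

#' Block-level ASM test between haplotypes
#'
#' For each block, sums methylated/unmethylated CpG call counts per
#' haplotype and applies a two-sided Fisher exact test. A block is
#' evaluable when it has at least `minCpgs` covered CpGs and an adjusted
#' CpG coverage (total counts / covered CpGs) of at least `minAdjCov` on
#' each haplotype. BH is computed across evaluable blocks of the call;
#' `is_asm` iff `q < fdr` and `|diff| > minDiff`, with `methylated_hap`
#' the higher-methylation haplotype of significant blocks.
#'
#' @param blocks [GenomicRanges::GRanges].
#' @param track haplotype-resolved [MethTrack-class].
#' @param minCpgs minimum covered CpGs per block (default 4).
#' @param minAdjCov minimum adjusted CpG coverage per haplotype
#'   (default 5).
#' @param minDiff ASM effect-size rule (default 0.4).
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame, one row per block: coordinates, per-haplotype
#'   count sums and adjusted coverages, `hap1_mean`, `hap2_mean`,
#'   `diff` (hap1 − hap2), `p`, `q`, `is_asm`, `methylated_hap`,
#'   `status`.
#' @export
blockASMTest <- function(blocks, track, minCpgs = 4L, minAdjCov = 5,
                         minDiff = 0.4, fdr = 0.05) {
  h1 <- .blockHapCounts(track, blocks, "hap1")
  h2 <- .blockHapCounts(track, blocks, "hap2")
  nCov <- pmax(h1$n_cpgs, h2$n_cpgs)
  adj1 <- ifelse(nCov > 0L, h1$total_sum / nCov, 0)
  adj2 <- ifelse(nCov > 0L, h2$total_sum / nCov, 0)
  out <- data.frame(chrom = as.character(seqnames(blocks)),
                    start = start(blocks), end = end(blocks),
                    n_cpgs = nCov,
                    hap1_meth = h1$meth_sum,
                    hap1_unmeth = h1$total_sum - h1$meth_sum,
                    hap2_meth = h2$meth_sum,
                    hap2_unmeth = h2$total_sum - h2$meth_sum,
                    adj_cov_hap1 = adj1, adj_cov_hap2 = adj2,
                    hap1_mean = h1$weighted_mean,
                    hap2_mean = h2$weighted_mean,
                    diff = h1$weighted_mean - h2$weighted_mean,
                    p = NA_real_, q = NA_real_, is_asm = FALSE,
                    methylated_hap = "none", status = "not_evaluable")
  eval <- nCov >= minCpgs & adj1 >= minAdjCov & adj2 >= minAdjCov
  if (any(eval)) {
    out$p[eval] <- fisherPvalue(out$hap1_meth[eval], out$hap1_unmeth[eval],
                                out$hap2_meth[eval], out$hap2_unmeth[eval])
    out$q[eval] <- bhAdjust(out$p[eval])
    out$status[eval] <- "evaluable"
    sig <- eval & !is.na(out$q) & out$q < fdr & abs(out$diff) > minDiff
    out$is_asm <- sig
    out$methylated_hap[sig] <- ifelse(out$diff[sig] > 0, "hap1", "hap2")
  }
  out
}

#' Block-level epimutation test against a pooled normal
#'
#' Compares the haplotype-combined (meth, unmeth) CpG count sums of each
#' block between a test sample and the pooled normal reference with a
#' two-sided Fisher exact test. Evaluable blocks need at least `minCpgs`
#' covered CpGs and adjusted CpG coverage of at least `minAdjCov` in
#' both the sample and the pooled normal. `is_epimutation` iff
#' `q < fdr` and `|diff| > minDiff`; `direction` follows the sign of
#' `diff` (sample − normal).
#'
#' @param blocks [GenomicRanges::GRanges].
#' @param sampleTrack,normalTrack [MethTrack-class] objects; `combined`
#'   records are used.
#' @param minCpgs,minAdjCov evaluability rules (defaults 4 and 5).
#' @param minDiff epimutation effect-size rule (default 0.3).
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame, one row per block: coordinates, count sums,
#'   `sample_mean`, `normal_mean`, `diff`, `p`, `q`, `is_epimutation`,
#'   `direction` in `{hyper, hypo, none}`, `status`.
#' @export
blockEpimutationTest <- function(blocks, sampleTrack, normalTrack,
                                 minCpgs = 4L, minAdjCov = 5,
                                 minDiff = 0.3, fdr = 0.05) {
  s <- .blockHapCounts(.combinedView(sampleTrack), blocks, NULL)
  r <- .blockHapCounts(.combinedView(normalTrack), blocks, NULL)
  adjS <- ifelse(s$n_cpgs > 0L, s$total_sum / s$n_cpgs, 0)
  adjR <- ifelse(r$n_cpgs > 0L, r$total_sum / r$n_cpgs, 0)
  out <- data.frame(chrom = as.character(seqnames(blocks)),
                    start = start(blocks), end = end(blocks),
                    n_cpgs = s$n_cpgs,
                    sample_meth = s$meth_sum,
                    sample_unmeth = s$total_sum - s$meth_sum,
                    normal_meth = r$meth_sum,
                    normal_unmeth = r$total_sum - r$meth_sum,
                    adj_cov_sample = adjS, adj_cov_normal = adjR,
                    sample_mean = s$weighted_mean,
                    normal_mean = r$weighted_mean,
                    diff = s$weighted_mean - r$weighted_mean,
                    p = NA_real_, q = NA_real_, is_epimutation = FALSE,
                    direction = "none", status = "not_evaluable")
  eval <- s$n_cpgs >= minCpgs & adjS >= minAdjCov & adjR >= minAdjCov
  if (any(eval)) {
    out$p[eval] <- fisherPvalue(out$sample_meth[eval],
                                out$sample_unmeth[eval],
                                out$normal_meth[eval],
                                out$normal_unmeth[eval])
    out$q[eval] <- bhAdjust(out$p[eval])
    out$status[eval] <- "evaluable"
    sig <- eval & !is.na(out$q) & out$q < fdr & abs(out$diff) > minDiff
    out$is_epimutation <- sig
    out$direction[sig] <- ifelse(out$diff[sig] > 0, "hyper", "hypo")
  }
  out
}

.BLOCK_STATES <- c("ASM_hap1_meth", "ASM_hap2_meth", "hyper", "hypo",
                   "intermediate", "indeterminate")

#' Classify per-block, per-sample state from the two block tests
#'
#' Precedence: a significant ASM call wins (`ASM_hap1_meth` /
#' `ASM_hap2_meth`); otherwise a significant epimutation gives
#' `hyper`/`hypo`; otherwise `intermediate` when the block's combined
#' mean lies in `[low, high]`, else `indeterminate`.
#'
#' @param asmCalls data.frame from [blockASMTest()].
#' @param epiCalls data.frame from [blockEpimutationTest()] on the same
#'   blocks, same order.
#' @param blockMean combined methylation mean per block (defaults to
#'   `epiCalls$sample_mean`).
#' @param low,high intermediate range (0.3, 0.7, inclusive).
#' @return character vector of states, one per block.
#' @export
classifyBlockState <- function(asmCalls, epiCalls, blockMean = NULL,
                               low = 0.3, high = 0.7) {
  stopifnot(nrow(asmCalls) == nrow(epiCalls))
  if (is.null(blockMean)) blockMean <- epiCalls$sample_mean
  state <- rep("indeterminate", nrow(asmCalls))
  mid <- !is.na(blockMean) & blockMean >= low & blockMean <= high
  state[mid] <- "intermediate"
  epi <- epiCalls$is_epimutation
  state[epi] <- epiCalls$direction[epi]
  asm <- asmCalls$is_asm
  state[asm] <- ifelse(asmCalls$methylated_hap[asm] == "hap1",
                       "ASM_hap1_meth", "ASM_hap2_meth")
  state
}
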