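## Sample-vs-pooled-normal DMR calling (documented stand-in caller),
## recurrence hotspots, intermediate-methylation flagging, and
## chromatin-state enrichment.
##
## The DMR caller is deliberately simple and fully parameterised: a
## per-CpG two-sided Fisher exact test on call counts, BH across tested
## CpGs, merging of significant CpGs into regions, and a region-level
## coverage-weighted effect-size filter. It is a stand-in for
## smoothed beta-binomial DMR callers and is validated on synthetic data
## only; the recurrence/hotspot logic downstream is the analysis of
## interest and is agnostic to the caller.

#' Call DMRs between a sample and a reference track
#'
#' Per-CpG two-sided Fisher exact test on (meth, unmeth) counts of the
#' CpGs covered in both tracks (autosomes only by default), BH across
#' tested CpGs; CpGs with `q < cpgFdr` and per-CpG difference
#' `|d| >= cpgMinDiff` are merged into regions with gap <= `mergeGap`;
#' a region is reported when it holds at least `minCpgs` significant
#' CpGs and its coverage-weighted mean difference exceeds `minDiff` in
#' absolute value. Region `p` is a Fisher test on region-aggregated
#' counts; region `q` is BH across reported regions.
#'
#' @param sampleTrack,referenceTrack [MethTrack-class] objects
#'   (`combined` haplotype records are used).
#' @param minDiff minimum |coverage-weighted methylation difference| for
#'   a region (default 0.3).
#' @param fdr region FDR threshold recorded in the output (default 0.05).
#' @param cpgFdr,cpgMinDiff per-CpG significance and effect filters
#'   (defaults 0.05 and 0.1).
#' @param mergeGap maximum gap between significant CpGs within one
#'   region, bases (default 300).
#' @param minCpgs minimum significant CpGs per region (default 3).
#' @param excludeChroms chromosomes excluded from testing (default
#'   chrX/chrY and plain X/Y).
#' @return data.frame of DMRs: coordinates, `n_cpgs`, `sample_mean`,
#'   `reference_mean`, `diff`, `p`, `q`.
#' @export
callDMRs <- function(sampleTrack, referenceTrack, minDiff = 0.3,
                     fdr = 0.05, cpgFdr = 0.05, cpgMinDiff = 0.1,
                     mergeGap = 300L, minCpgs = 3L,
                     excludeChroms = c("chrX", "chrY", "X", "Y")) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      sample_mean = numeric(), reference_mean = numeric(),
                      diff = numeric(), p = numeric(), q = numeric())
  s <- hapTrack(sampleTrack, "combined")
  r <- hapTrack(referenceTrack, "combined")
  sg <- cpgRanges(s); rg <- cpgRanges(r)
  skey <- paste(as.character(seqnames(sg)), start(sg))
  rkey <- paste(as.character(seqnames(rg)), start(rg))
  common <- intersect(skey, rkey)
  if (!length(common)) return(empty)
  si <- match(common, skey); ri <- match(common, rkey)
  chrom <- as.character(seqnames(sg))[si]
  keep <- !(chrom %in% excludeChroms)
  si <- si[keep]; ri <- ri[keep]; chrom <- chrom[keep]
  pos <- start(sg)[si]
  sm <- methCounts(s)[si]; st <- totalCounts(s)[si]
  rm_ <- methCounts(r)[ri]; rt <- totalCounts(r)[ri]
  cov <- st > 0L & rt > 0L
  if (!any(cov)) return(empty)
  chrom <- chrom[cov]; pos <- pos[cov]
  sm <- sm[cov]; st <- st[cov]; rm_ <- rm_[cov]; rt <- rt[cov]
  p <- fisherPvalue(sm, st - sm, rm_, rt - rm_)
  q <- bhAdjust(p)
  d <- sm / st - rm_ / rt
  sig <- q < cpgFdr & abs(d) >= cpgMinDiff
  if (!any(sig)) return(empty)
  sigGr <- GRanges(chrom[sig], IRanges(pos[sig], width = 1L))
  ## positions <= mergeGap bp apart share a region (width-1 ranges have
  ## inter-position gapwidth d-1)
  regions <- reduce(sigGr, min.gapwidth = as.integer(mergeGap))
  nSig <- countOverlaps(regions, sigGr)
  regions <- regions[nSig >= minCpgs]
  if (!length(regions)) return(empty)
  aggS <- aggregateIntervals(s, regions)
  aggR <- aggregateIntervals(r, regions)
  diff <- aggS$weighted_mean - aggR$weighted_mean
  keepR <- !is.na(diff) & abs(diff) > minDiff
  if (!any(keepR)) return(empty)
  regions <- regions[keepR]
  aggS <- aggS[keepR, ]; aggR <- aggR[keepR, ]
  pReg <- fisherPvalue(aggS$meth_sum, aggS$total_sum - aggS$meth_sum,
                       aggR$meth_sum, aggR$total_sum - aggR$meth_sum)
  data.frame(chrom = as.character(seqnames(regions)),
             start = start(regions), end = end(regions),
             n_cpgs = aggS$n_cpgs,
             sample_mean = aggS$weighted_mean,
             reference_mean = aggR$weighted_mean,
             diff = diff[keepR], p = pReg, q = bhAdjust(pReg))
}

#' Convert a DMR data.frame to GRanges
#' @param dmrs data.frame from [callDMRs()] (needs chrom/start/end).
#' @return [GenomicRanges::GRanges].
#' @export
dmrRanges <- function(dmrs) {
  if (!nrow(dmrs)) return(GRanges())
  GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
}

#' Recurrence hotspots across per-sample DMR sets
#'
#' Multi-intersects the per-sample merged DMR sets, keeps segments
#' overlapped by DMRs from at least `minRecurrence` samples (a sample
#' counts once however many of its DMRs overlap), merges adjacent
#' retained segments, and drops regions containing fewer than `minCpgs`
#' CpGs of `track` (by convention the pooled normal track).
#'
#' @param dmrSets list of per-sample DMR interval sets
#'   ([GenomicRanges::GRanges] or [callDMRs()] data.frames).
#' @param minRecurrence minimum number of samples (default 25).
#' @param minCpgs minimum CpGs inside a hotspot (default 5).
#' @param track [MethTrack-class] supplying CpG positions for the CpG
#'   filter; `NULL` skips that filter.
#' @return [GenomicRanges::GRanges] of hotspots with metadata columns
#'   `recurrence` (samples with an overlapping DMR) and `n_cpgs`.
#' @export
findHotspots <- function(dmrSets, minRecurrence = 25L, minCpgs = 5L,
                         track = NULL) {
  sets <- lapply(dmrSets, function(x)
    if (is(x, "GRanges")) reduce(granges(x)) else reduce(dmrRanges(x)))
  seg <- multiIntersect(sets)
  seg <- seg[mcols(seg)$count >= minRecurrence]
  if (!length(seg)) {
    out <- GRanges()
    mcols(out)$recurrence <- integer(); mcols(out)$n_cpgs <- integer()
    return(out)
  }
  hot <- reduce(granges(seg), min.gapwidth = 1L)
  rec <- Reduce(`+`, lapply(sets, function(g)
    as.integer(countOverlaps(hot, g) > 0L)))
  mcols(hot)$recurrence <- rec
  if (!is.null(track)) {
    nC <- countOverlaps(hot, cpgRanges(hapTrack(track, "combined")))
    mcols(hot)$n_cpgs <- nC
    hot <- hot[nC >= minCpgs]
  } else {
    mcols(hot)$n_cpgs <- NA_integer_
  }
  hot
}

#' Flag regions with intermediate methylation in a normal track
#'
#' A region is an IMR iff its coverage-weighted mean methylation in the
#' normal track lies in the inclusive range `[low, high]`; regions with
#' zero coverage are `indeterminate`.
#'
#' @param regions [GenomicRanges::GRanges].
#' @param normalTrack [MethTrack-class].
#' @param low,high inclusive bounds (defaults 0.3 and 0.7).
#' @return data.frame: coordinates, `weighted_mean`, `imr_flag` in
#'   `{"IMR", "not_IMR", "indeterminate"}`.
#' @export
flagIntermediate <- function(regions, normalTrack, low = 0.3, high = 0.7) {
  agg <- aggregateIntervals(normalTrack, regions)
  flag <- ifelse(is.na(agg$weighted_mean), "indeterminate",
                 ifelse(agg$weighted_mean >= low &
                          agg$weighted_mean <= high, "IMR", "not_IMR"))
  data.frame(chrom = agg$chrom, start = agg$start, end = agg$end,
             weighted_mean = agg$weighted_mean, imr_flag = flag)
}

#' Chromatin-state enrichment of a block set
#'
#' Fold enrichment of block base pairs in each chromatin state relative
#' to the state's share of the genome:
#' `fold = (block bp in state / total block bp) / (state bp / genomeSpan)`.
#'
#' @param blocks [GenomicRanges::GRanges] of blocks.
#' @param states [GenomicRanges::GRanges] with a metadata column `name`
#'   (or `state`) giving the chromatin-state label of each interval.
#' @param genomeSpan total genome length in bases for the background.
#' @return data.frame: `state`, `block_bp`, `state_bp`,
#'   `block_fraction`, `background_fraction`, `fold` (`NA` and
#'   `undefined_background = TRUE` for states with zero background bp).
#' @export
stateEnrichment <- function(blocks, states, genomeSpan) {
  stopifnot(genomeSpan > 0)
  lab <- mcols(states)$name
  if (is.null(lab)) lab <- mcols(states)$state
  stopifnot(!is.null(lab))
  blocks <- reduce(granges(blocks))
  blockBp <- sum(width(blocks))
  out <- lapply(unique(lab), function(st) {
    sgr <- reduce(granges(states[lab == st]))
    stBp <- sum(width(sgr))
    inBp <- sum(width(GenomicRanges::intersect(blocks, sgr)))
    bf <- if (blockBp > 0) inBp / blockBp else NA_real_
    gf <- stBp / genomeSpan
    data.frame(state = st, block_bp = inBp, state_bp = stBp,
               block_fraction = bf, background_fraction = gf,
               fold = if (gf > 0 && !is.na(bf)) bf / gf else NA_real_,
               undefined_background = gf == 0)
  })
  do.call(rbind, out)
}
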