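## Tissue-specific IMR definition from multi-tissue normal block sets,
## and per-region-class epimutation rates in tumors.

#' Blocks consistently present in all samples of each tissue
#'
#' Within each tissue, a block is retained iff it overlaps (>= 1 bp) a
#' block in every sample's set; retained blocks are merged per tissue
#' with the 50 bp minimum-size / 50 bp minimum-gap rule.
#'
#' @param sampleSets either a list of per-sample
#'   [GenomicRanges::GRanges] (one tissue) or a named list of such
#'   lists (tissue -> samples).
#' @param minSize,maxGap merge rules in bases (defaults 50 and 50).
#' @return [GenomicRanges::GRanges] with metadata column `tissue`
#'   (`"all"` for the single-tissue form).
#' @export
consistentBlocks <- function(sampleSets, minSize = 50L, maxGap = 50L) {
  if (length(sampleSets) && is(sampleSets[[1L]], "GRanges"))
    sampleSets <- list(all = sampleSets)
  out <- lapply(names(sampleSets), function(ts) {
    sets <- sampleSets[[ts]]
    stopifnot(length(sets) >= 1L)
    cand <- reduce(unlist(GRangesList(lapply(sets, granges))))
    inAll <- Reduce(`&`, lapply(sets, function(s) overlapsAny(cand, s)))
    kept <- mergeIntervals(cand[inAll], maxGap = maxGap,
                           minSize = minSize)
    if (length(kept)) mcols(kept)$tissue <- ts
    kept
  })
  out <- out[vapply(out, length, 1L) > 0L]
  if (!length(out)) {
    g <- GRanges(); mcols(g)$tissue <- character(); return(g)
  }
  sort(unlist(GRangesList(out)))
}

#' Tissue-specific intermediately methylated blocks
#'
#' A candidate block (with a `tissue` metadata column naming its matched
#' tissue) is kept iff, over the matched-tissue samples, the mean of the
#' per-sample weighted methylation means lies in `[low, high]` with a
#' coefficient of variation (sample sd / mean, n-1 denominator) at most
#' `maxCV`, and the absolute difference between the matched mean and the
#' average over all non-matched samples' means is at least `minDelta`.
#' The delta rule is what removes germline-imprint-like blocks that are
#' intermediate in every tissue.
#'
#' @param candidates [GenomicRanges::GRanges] with metadata column
#'   `tissue`.
#' @param tracksByTissue named list: tissue -> list of
#'   [MethTrack-class] normal samples.
#' @param low,high intermediate range (0.3, 0.7).
#' @param maxCV maximum coefficient of variation in the matched tissue
#'   (default 0.5).
#' @param minDelta minimum |matched mean − non-matched mean|
#'   (default 0.2).
#' @return list: `blocks` (kept `GRanges` with `matched_mean`,
#'   `matched_cv`, `other_mean`, `delta`) and `excluded` (data.frame
#'   with a `reason` per dropped candidate).
#' @export
tissueSpecificIMRs <- function(candidates, tracksByTissue, low = 0.3,
                               high = 0.7, maxCV = 0.5, minDelta = 0.2) {
  stopifnot(!is.null(mcols(candidates)$tissue),
            all(mcols(candidates)$tissue %in% names(tracksByTissue)))
  allTissues <- names(tracksByTissue)
  ## per-sample weighted means for every candidate, tissue by tissue
  meansBySample <- lapply(allTissues, function(ts)
    matrix(vapply(tracksByTissue[[ts]], function(tr)
      aggregateIntervals(tr, candidates)$weighted_mean,
      numeric(length(candidates))), nrow = length(candidates)))
  names(meansBySample) <- allTissues
  n <- length(candidates)
  matchedMean <- matchedCV <- otherMean <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ts <- mcols(candidates)$tissue[i]
    mm <- meansBySample[[ts]][i, ]
    om <- unlist(lapply(setdiff(allTissues, ts), function(o)
      meansBySample[[o]][i, ]))
    if (any(is.na(mm)) || any(is.na(om))) {
      reason[i] <- "zero_coverage"
      next
    }
    matchedMean[i] <- mean(mm)
    matchedCV[i] <- if (length(mm) > 1L && matchedMean[i] > 0)
      sd(mm) / matchedMean[i] else 0
    otherMean[i] <- mean(om)
    delta <- abs(matchedMean[i] - otherMean[i])
    if (matchedMean[i] < low || matchedMean[i] > high)
      reason[i] <- "outside_range"
    else if (matchedCV[i] > maxCV)
      reason[i] <- "cv_too_high"
    else if (delta < minDelta)
      reason[i] <- "delta_too_small"
  }
  keep <- is.na(reason)
  blocks <- candidates[keep]
  mcols(blocks)$matched_mean <- matchedMean[keep]
  mcols(blocks)$matched_cv <- matchedCV[keep]
  mcols(blocks)$other_mean <- otherMean[keep]
  mcols(blocks)$delta <- abs(matchedMean[keep] - otherMean[keep])
  dropped <- candidates[!keep]
  list(blocks = blocks,
       excluded = data.frame(chrom = as.character(seqnames(dropped)),
                             start = start(dropped), end = end(dropped),
                             tissue = mcols(dropped)$tissue,
                             reason = reason[!keep]))
}

#' Epimutation rates per region class
#'
#' For each tumor sample and region class, runs the block-level
#' epimutation test ([blockEpimutationTest()]; BH per class per sample)
#' and reports the percentage of regions with a significant epimutation,
#' over evaluable regions and over all regions of the class.
#'
#' @param regionSetsByClass named list: class -> [GenomicRanges::GRanges]
#'   (e.g. IMR_blocks, CpG_islands, TSS, enhancers).
#' @param tumorTracks named list of tumor [MethTrack-class] objects.
#' @param normalTrack pooled matched-normal [MethTrack-class].
#' @param ... passed to [blockEpimutationTest()].
#' @return data.frame: `sample`, `class`, `n_regions`, `n_evaluable`,
#'   `n_differential`, `percent_evaluable`, `percent_all`
#'   (`NA` percentages when nothing is evaluable).
#' @export
regionClassEpimutationRates <- function(regionSetsByClass, tumorTracks,
                                        normalTrack, ...) {
  stopifnot(length(regionSetsByClass) >= 1L, length(tumorTracks) >= 1L)
  if (is.null(names(tumorTracks)))
    names(tumorTracks) <- vapply(tumorTracks, sampleId, "")
  rows <- list()
  for (sm in names(tumorTracks)) {
    for (cl in names(regionSetsByClass)) {
      regions <- regionSetsByClass[[cl]]
      calls <- blockEpimutationTest(regions, tumorTracks[[sm]],
                                    normalTrack, ...)
      nEval <- sum(calls$status == "evaluable")
      nDiff <- sum(calls$is_epimutation)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sm, class = cl, n_regions = length(regions),
        n_evaluable = nEval, n_differential = nDiff,
        percent_evaluable = if (nEval) 100 * nDiff / nEval else NA_real_,
        percent_all = if (length(regions)) 100 * nDiff / length(regions)
                      else NA_real_)
    }
  }
  do.call(rbind, rows)
}
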