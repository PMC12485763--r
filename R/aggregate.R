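## Coverage-weighted aggregation of CpG counts over intervals, and
## pooling of samples. The weighted mean is the count ratio
## meth_sum/total_sum, never the mean of per-CpG fractions.

#' Aggregate CpG counts over intervals
#'
#' For each interval, sums methylated and total call counts of the CpGs
#' it contains (half-open membership on the on-disk scale; a CpG belongs
#' to exactly one interval of a partition) and reports the
#' coverage-weighted mean methylation `meth_sum / total_sum`. Intervals
#' with no covered CpG get `NA` (missing, not 0) so downstream filters
#' can distinguish "unmethylated" from "unobserved".
#'
#' @param track a [MethTrack-class].
#' @param regions [GenomicRanges::GRanges] of intervals.
#' @param haplotype restrict to one haplotype label, or `NULL` to use all
#'   records (summing across haplotypes).
#' @return data.frame with one row per region: `chrom`, `start`, `end`
#'   (1-based closed, as in `regions`), `n_cpgs`, `meth_sum`, `total_sum`,
#'   `weighted_mean`.
#' @examples
#' tr <- MethTrack("s", "chrS", c(10, 20), meth = c(1L, 9L),
#'                 unmeth = c(1L, 1L))
#' rg <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1, 100))
#' aggregateIntervals(tr, rg)$weighted_mean  # 10/12, not 0.7
#' @export
aggregateIntervals <- function(track, regions, haplotype = NULL) {
  stopifnot(is(track, "MethTrack"), is(regions, "GRanges"))
  if (!is.null(haplotype)) track <- hapTrack(track, haplotype)
  gr <- cpgRanges(track)
  meth <- methCounts(track); tot <- totalCounts(track)
  n <- length(regions)
  out <- data.frame(chrom = as.character(seqnames(regions)),
                    start = start(regions), end = end(regions),
                    n_cpgs = 0L, meth_sum = 0L, total_sum = 0L,
                    weighted_mean = NA_real_)
  if (length(gr) && n) {
    hits <- findOverlaps(gr, regions)
    if (length(hits)) {
      q <- queryHits(hits); s <- subjectHits(hits)
      covered <- tot[q] > 0L
      sc <- s[covered]; pc <- start(gr)[q][covered]
      keep <- !duplicated(paste(sc, pc))
      out$n_cpgs <- as.integer(tabulate(sc[keep], n))
      ms <- tapply(meth[q], s, sum); ts <- tapply(tot[q], s, sum)
      idx <- as.integer(names(ts))
      out$meth_sum[idx] <- as.integer(ms)
      out$total_sum[idx] <- as.integer(ts)
    }
  }
  out$weighted_mean <- ifelse(out$total_sum > 0L,
                              out$meth_sum / out$total_sum, NA_real_)
  out
}

#' Pool methylation tracks by summing counts per CpG
#'
#' Outer-join semantics: a (chrom, pos, haplotype) key present in only
#' one track is carried through unchanged; shared keys get the count sum.
#'
#' @param tracks list of [MethTrack-class] objects.
#' @param sampleId identifier for the pooled track (default `"pooled"`).
#' @return a [MethTrack-class].
#' @export
poolTracks <- function(tracks, sampleId = "pooled") {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, is, TRUE, "MethTrack")))
  if (length(tracks) == 1L) {
    t1 <- tracks[[1L]]
    return(new("MethTrack", sampleId = sampleId, cpgs = cpgRanges(t1)))
  }
  dfs <- lapply(tracks, function(t) {
    gr <- cpgRanges(t)
    data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
               haplotype = haplotypes(t), meth = methCounts(t),
               unmeth = unmethCounts(t))
  })
  df <- do.call(rbind, dfs)
  key <- paste(df$chrom, df$pos, df$haplotype)
  meth <- tapply(df$meth, key, sum)
  unmeth <- tapply(df$unmeth, key, sum)
  first <- df[!duplicated(key), c("chrom", "pos", "haplotype")]
  k <- paste(first$chrom, first$pos, first$haplotype)
  MethTrack(sampleId, chrom = first$chrom, pos = first$pos,
            meth = as.integer(meth[k]), unmeth = as.integer(unmeth[k]),
            haplotype = first$haplotype)
}
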