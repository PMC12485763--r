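## Independent oracles and small fixture builders used across the suite.
## These deliberately avoid the package's own code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## exhaustive hypergeometric enumeration of the two-sided Fisher p for a
## 2x2 table [[a, b], [c, d]] (rows = groups, cols = outcomes)
enumFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(r1 + r2, c1)
  probs <- exp(logp)
  pObs <- probs[match(a, support)]
  ## probability-mass rule with the standard relative-error guard
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## naive sort-based Benjamini-Hochberg step-up
naiveBH <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## textbook Pearson correlation squared on two numeric vectors
pearsonR2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  if (den <= 0) return(NA_real_)
  num^2 / den
}

## per-base brute-force coverage count over a list of interval sets
bruteCoverageCounts <- function(sets, at) {
  vapply(at, function(b) {
    sum(vapply(sets, function(gr)
      any(start(gr) <= b & end(gr) >= b), TRUE))
  }, 1L)
}

## MethReads from pattern strings like "MMUU" laid over `positions`;
## reads may carry allele/haplotype tags (recycled)
readsFromPatterns <- function(patterns, positions, chrom = "chrS",
                              allele = "none", hap = "none",
                              sampleId = "fix") {
  allele <- rep_len(allele, length(patterns))
  hap <- rep_len(hap, length(patterns))
  rows <- lapply(seq_along(patterns), function(i) {
    calls <- strsplit(patterns[i], "")[[1]]
    stopifnot(length(calls) <= length(positions))
    data.frame(read_id = sprintf("r%04d", i), chrom = chrom,
               pos = positions[seq_along(calls)], call = calls,
               allele_tag = allele[i], hap_tag = hap[i])
  })
  MethReads(sampleId, do.call(rbind, rows))
}

## MethTrack over one chromosome from count vectors
trackFromCounts <- function(pos, meth, total, sampleId = "t",
                            chrom = "chrS", haplotype = "combined") {
  MethTrack(sampleId, chrom, pos, meth = meth, unmeth = total - meth,
            haplotype = haplotype)
}

## haplotype-resolved track with constant per-CpG depth and per-hap
## methylation probabilities drawn as exact counts round(p * depth)
hapTrackExact <- function(pos, p1, p2, depth, sampleId = "hap",
                          chrom = "chrS") {
  m1 <- round(rep_len(p1, length(pos)) * depth)
  m2 <- round(rep_len(p2, length(pos)) * depth)
  MethTrack(sampleId, chrom, c(pos, pos),
            meth = c(m1, m2), unmeth = c(depth - m1, depth - m2),
            haplotype = rep(c("hap1", "hap2"), each = length(pos)))
}

grS <- function(start, end, chrom = "chrS") {
  GRanges(chrom, IRanges(start, end))
}
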