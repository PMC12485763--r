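## Fragment-level heterogeneity metrics, read classification,
## SNP-partitioned ASM testing, and mLD-based methylation-haplotype-block
## discovery from per-read CpG calls.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (ties share the smaller
#' adjusted value, q capped at 1), as used for every multiple-testing
#' family in this package. Thin wrapper over [stats::p.adjust].
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @return q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  stopifnot(is.numeric(p))
  if (!length(p)) return(numeric())
  p.adjust(p, method = "BH")
}

#' Two-sided Fisher exact p-values for 2x2 count tables
#'
#' Vectorised over tables `[[m1, u1], [m2, u2]]`; each table is tested
#' with [stats::fisher.test] (conditional exact test, two-sided by the
#' probability-mass rule).
#'
#' @param m1,u1,m2,u2 non-negative integer vectors (recycled).
#' @return numeric vector of p-values.
#' @examples
#' fisherPvalue(9, 1, 1, 9)  # 202/184756
#' @export
fisherPvalue <- function(m1, u1, m2, u2) {
  n <- max(length(m1), length(u1), length(m2), length(u2))
  m1 <- rep_len(as.integer(m1), n); u1 <- rep_len(as.integer(u1), n)
  m2 <- rep_len(as.integer(m2), n); u2 <- rep_len(as.integer(u2), n)
  stopifnot(all(c(m1, u1, m2, u2) >= 0L))
  vapply(seq_len(n), function(i) {
    if (m1[i] + u1[i] == 0L || m2[i] + u2[i] == 0L) return(NA_real_)
    fisher.test(matrix(c(m1[i], u1[i], m2[i], u2[i]), 2L,
                       byrow = TRUE))$p.value
  }, numeric(1))
}

## in-region calls, as a read x position logical (TRUE = methylated) matrix
.callMatrix <- function(reads, region = NULL, positions = NULL) {
  df <- readCalls(reads)
  if (!is.null(region)) {
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    df <- df[df$chrom == as.character(seqnames(region)) &
               df$pos >= start(region) & df$pos <= end(region), ,
             drop = FALSE]
  }
  if (is.null(positions)) positions <- sort(unique(df$pos))
  df <- df[df$pos %in% positions, , drop = FALSE]
  ids <- unique(df$read_id)
  m <- matrix(NA, nrow = length(ids), ncol = length(positions),
              dimnames = list(ids, as.character(positions)))
  if (nrow(df))
    m[cbind(match(df$read_id, ids), match(df$pos, positions))] <-
      df$call == "M"
  m
}

#' Classify reads over a region as methylated/unmethylated/undetermined
#'
#' A read's in-region methylated fraction `f` maps to `methylated` when
#' `f >= upper` (default 0.7), `unmethylated` when `f <= lower` (default
#' 0.3), and `undetermined` otherwise. Reads with zero in-region calls do
#' not appear in the output (excluded, not classified).
#'
#' @param reads a [MethReads-class].
#' @param region a single-interval [GenomicRanges::GRanges].
#' @param lower,upper classification thresholds on the methylated
#'   fraction.
#' @return data.frame with one row per overlapping read: `read_id`,
#'   `n_calls`, `frac_meth`, `class`, `allele_tag`, `hap_tag`.
#' @export
classifyReads <- function(reads, region, lower = 0.3, upper = 0.7) {
  m <- .callMatrix(reads, region)
  if (!nrow(m))
    return(data.frame(read_id = character(), n_calls = integer(),
                      frac_meth = numeric(), class = character(),
                      allele_tag = character(), hap_tag = character()))
  n <- rowSums(!is.na(m))
  f <- rowSums(m, na.rm = TRUE) / n
  cls <- ifelse(f >= upper, "methylated",
                ifelse(f <= lower, "unmethylated", "undetermined"))
  df <- readCalls(reads)
  tag <- df[!duplicated(df$read_id), c("read_id", "allele_tag", "hap_tag")]
  out <- data.frame(read_id = rownames(m), n_calls = as.integer(n),
                    frac_meth = f, class = cls)
  out$allele_tag <- tag$allele_tag[match(out$read_id, tag$read_id)]
  out$hap_tag <- tag$hap_tag[match(out$read_id, tag$read_id)]
  rownames(out) <- NULL
  out
}

.patternEntropy <- function(pats) {
  tab <- table(pats)
  p <- tab / sum(tab)
  -sum(p * log2(p))
}

#' Fragment-level methylation heterogeneity metrics
#'
#' Computes, over the reads overlapping one region (reads with fewer than
#' two in-region calls are excluded):
#' \describe{
#'   \item{pdr}{proportion of discordant reads (reads carrying both M and
#'     U calls).}
#'   \item{entropy}{Shannon entropy (bits) of read methylation patterns in
#'     4-CpG windows, averaged over windows with fully-covering reads.}
#'   \item{chalm}{fraction of reads with at least one methylated call.}
#'   \item{mhl}{methylation haplotype load: length-weighted (w_l = l)
#'     average of the fully-methylated fraction of l-CpG stretches,
#'     l = 1..region CpG count.}
#'   \item{mcr}{methylation concordance ratio: fraction of within-read
#'     adjacent call pairs that agree.}
#'   \item{mbs}{methylation block score: per-read sum of squared
#'     methylated-run lengths over squared call count, averaged.}
#'   \item{mean_adjacent_r2}{mean of defined adjacent-pair mLD r-squared
#'     (see [adjacentMLD()]).}
#' }
#'
#' @param reads a [MethReads-class].
#' @param region single-interval [GenomicRanges::GRanges].
#' @param minPairReads minimum reads per CpG pair for the r-squared
#'   component.
#' @return one-row data.frame of the metrics plus `n_reads`; all-`NA`
#'   when no read qualifies.
#' @export
fragmentMetrics <- function(reads, region, minPairReads = 10L) {
  m <- .callMatrix(reads, region)
  m <- m[rowSums(!is.na(m)) >= 2L, , drop = FALSE]
  na <- data.frame(pdr = NA_real_, entropy = NA_real_, chalm = NA_real_,
                   mhl = NA_real_, mcr = NA_real_, mbs = NA_real_,
                   mean_adjacent_r2 = NA_real_, n_reads = 0L)
  if (!nrow(m)) return(na)
  nM <- rowSums(m, na.rm = TRUE)
  nC <- rowSums(!is.na(m))
  pdr <- mean(nM > 0L & nM < nC)
  chalm <- mean(nM > 0L)

  ## entropy over sliding 4-CpG windows (whole region when < 4 CpGs)
  L <- ncol(m)
  win <- if (L >= 4L) lapply(seq_len(L - 3L), function(i) i:(i + 3L))
         else list(seq_len(L))
  ent <- vapply(win, function(w) {
    sub <- m[, w, drop = FALSE]
    full <- rowSums(!is.na(sub)) == length(w)
    if (!any(full)) return(NA_real_)
    pats <- apply(sub[full, , drop = FALSE], 1L,
                  function(r) paste(as.integer(r), collapse = ""))
    .patternEntropy(pats)
  }, numeric(1))
  entropy <- if (all(is.na(ent))) NA_real_ else mean(ent, na.rm = TRUE)

  ## MHL over stretches of l consecutive region CpGs, weights w_l = l
  num <- 0; den <- 0
  for (l in seq_len(L)) {
    cov <- 0L; fullM <- 0L
    for (i in seq_len(L - l + 1L)) {
      sub <- m[, i:(i + l - 1L), drop = FALSE]
      ok <- rowSums(!is.na(sub)) == l
      cov <- cov + sum(ok)
      fullM <- fullM + sum(ok & rowSums(sub, na.rm = TRUE) == l)
    }
    if (cov > 0L) { num <- num + l * fullM / cov; den <- den + l }
  }
  mhl <- if (den > 0) num / den else NA_real_

  ## MCR / MBS per read
  conc <- 0L; pairs <- 0L; mbs_i <- numeric(nrow(m))
  for (r in seq_len(nrow(m))) {
    v <- m[r, ][!is.na(m[r, ])]
    if (length(v) >= 2L) {
      d <- v[-1L] == v[-length(v)]
      conc <- conc + sum(d); pairs <- pairs + length(d)
    }
    runs <- rle(v)
    mruns <- runs$lengths[runs$values]
    mbs_i[r] <- sum(mruns^2) / length(v)^2
  }
  mcr <- if (pairs > 0L) conc / pairs else NA_real_
  mbs <- mean(mbs_i)

  ld <- adjacentMLD(reads, region = region, minPairReads = minPairReads)
  r2 <- ld$r2[!is.na(ld$r2)]
  data.frame(pdr = pdr, entropy = entropy, chalm = chalm, mhl = mhl,
             mcr = mcr, mbs = mbs,
             mean_adjacent_r2 = if (length(r2)) mean(r2) else NA_real_,
             n_reads = nrow(m))
}

#' Pool per-read call sets from several samples
#'
#' Concatenates the call tables of multiple [MethReads-class] objects
#' (read identifiers must not collide), the input expected by
#' [adjacentMLD()] when blocks are discovered from reads pooled across
#' samples, as is standard for mLD block finding.
#'
#' @param readsList list of [MethReads-class] objects.
#' @param sampleId identifier for the pooled object.
#' @return a [MethReads-class].
#' @export
poolReads <- function(readsList, sampleId = "pooled") {
  stopifnot(length(readsList) >= 1L,
            all(vapply(readsList, is, TRUE, "MethReads")))
  MethReads(sampleId, do.call(rbind, lapply(readsList, readCalls)))
}

#' Methylation linkage disequilibrium between adjacent CpGs
#'
#' For every pair of adjacent CpG positions, computes the squared Pearson
#' correlation of the two binary call vectors over the reads covering
#' both positions (mLD r-squared). Pairs with fewer than `minPairReads`
#' co-covering reads, or with a zero-variance member, get `NA`.
#'
#' @param reads a [MethReads-class].
#' @param positions optional integer vector (single chromosome, with
#'   `chrom`) or [GenomicRanges::GRanges] of CpG sites defining
#'   adjacency; defaults to the positions observed in `reads`.
#' @param region optional single interval restricting the computation.
#' @param chrom chromosome for a plain `positions` vector.
#' @param minPairReads minimum co-covering reads per pair (default 10).
#' @return data.frame: `chrom`, `pos_a`, `pos_b`, `n_reads`, `r2`.
#' @export
adjacentMLD <- function(reads, positions = NULL, region = NULL,
                        chrom = NULL, minPairReads = 10L) {
  df <- readCalls(reads)
  if (!is.null(region)) {
    stopifnot(length(region) == 1L)
    df <- df[df$chrom == as.character(seqnames(region)) &
               df$pos >= start(region) & df$pos <= end(region), ,
             drop = FALSE]
  }
  posByChrom <-
    if (is.null(positions)) {
      split(df$pos, df$chrom)
    } else if (is(positions, "GRanges")) {
      split(start(positions), as.character(seqnames(positions)))
    } else {
      stopifnot(!is.null(chrom))
      stats::setNames(list(as.integer(positions)), chrom)
    }
  res <- lapply(names(posByChrom), function(ch) {
    pos <- sort(unique(posByChrom[[ch]]))
    if (length(pos) < 2L) return(NULL)
    sub <- df[df$chrom == ch & df$pos %in% pos, , drop = FALSE]
    ids <- unique(sub$read_id)
    m <- matrix(NA, length(ids), length(pos))
    if (nrow(sub))
      m[cbind(match(sub$read_id, ids), match(sub$pos, pos))] <-
        sub$call == "M"
    k <- length(pos) - 1L
    r2 <- rep(NA_real_, k); nr <- integer(k)
    for (i in seq_len(k)) {
      x <- m[, i]; y <- m[, i + 1L]
      ok <- !is.na(x) & !is.na(y)
      nr[i] <- sum(ok)
      if (nr[i] >= minPairReads) {
        xs <- as.numeric(x[ok]); ys <- as.numeric(y[ok])
        if (sd(xs) > 0 && sd(ys) > 0) r2[i] <- cor(xs, ys)^2
      }
    }
    data.frame(chrom = ch, pos_a = pos[-length(pos)], pos_b = pos[-1L],
               n_reads = nr, r2 = r2)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(chrom = character(), pos_a = integer(),
                      pos_b = integer(), n_reads = integer(),
                      r2 = numeric()))
  do.call(rbind, res)
}

#' Methylation haplotype blocks from adjacent-pair mLD
#'
#' A block is a maximal run of consecutive CpGs in which every adjacent
#' pair has a defined r-squared at or above the threshold; runs with at
#' least `minCpgs` CpGs (default 4) are reported. An undefined pair
#' (too few reads or zero variance) breaks a run.
#'
#' @param pairLD data.frame from [adjacentMLD()].
#' @param r2Threshold minimum adjacent-pair r-squared (default 0.5).
#' @param minCpgs minimum CpGs per block (default 4).
#' @return [GenomicRanges::GRanges] of blocks with metadata columns
#'   `n_cpgs`, `min_r2`, and `cpg_pos` (an [IRanges::IntegerList]).
#' @export
findBlocks <- function(pairLD, r2Threshold = 0.5, minCpgs = 4L) {
  empty <- GRanges()
  mcols(empty)$n_cpgs <- integer()
  mcols(empty)$min_r2 <- numeric()
  mcols(empty)$cpg_pos <- IRanges::IntegerList()
  if (!nrow(pairLD)) return(empty)
  out <- list()
  for (ch in unique(pairLD$chrom)) {
    sub <- pairLD[pairLD$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos_a), , drop = FALSE]
    ## pairs must chain consecutively: pos_b of i == pos_a of i+1
    ok <- !is.na(sub$r2) & sub$r2 >= r2Threshold
    chained <- c(sub$pos_a[-1L] == sub$pos_b[-nrow(sub)], FALSE)
    i <- 1L
    while (i <= nrow(sub)) {
      if (!ok[i]) { i <- i + 1L; next }
      j <- i
      while (j < nrow(sub) && chained[j] && ok[j + 1L]) j <- j + 1L
      nC <- j - i + 2L
      if (nC >= minCpgs) {
        pos <- c(sub$pos_a[i:j], sub$pos_b[j])
        out[[length(out) + 1L]] <- list(chrom = ch, pos = pos,
                                        min_r2 = min(sub$r2[i:j]))
      }
      i <- j + 1L
    }
  }
  if (!length(out)) return(empty)
  gr <- GRanges(vapply(out, `[[`, "", "chrom"),
                IRanges(vapply(out, function(b) as.integer(min(b$pos)), 1L),
                        vapply(out, function(b) as.integer(max(b$pos)), 1L)))
  mcols(gr)$n_cpgs <- vapply(out, function(b) length(b$pos), 1L)
  mcols(gr)$min_r2 <- vapply(out, `[[`, 1, "min_r2")
  mcols(gr)$cpg_pos <- IRanges::IntegerList(lapply(out, function(b)
    as.integer(b$pos)))
  sort(gr)
}

#' Select IMR blocks: methylation haplotype blocks intermediate in all
#' normal samples
#'
#' A block is retained iff its coverage-weighted mean methylation lies in
#' `[low, high]` in every normal track; a block with zero coverage in any
#' normal is excluded with reason `"zero_coverage"`.
#'
#' @param blocks [GenomicRanges::GRanges] of candidate blocks.
#' @param normalTracks list of [MethTrack-class] normal samples.
#' @param low,high inclusive intermediate-methylation bounds (0.3, 0.7).
#' @return list with `blocks` (retained `GRanges`, per-sample means as
#'   metadata columns `mean_<sampleId>`) and `excluded` (data.frame of
#'   dropped blocks with a `reason`).
#' @export
selectIMRBlocks <- function(blocks, normalTracks, low = 0.3, high = 0.7) {
  stopifnot(length(normalTracks) >= 1L)
  means <- vapply(normalTracks, function(tr)
    aggregateIntervals(tr, blocks)$weighted_mean, numeric(length(blocks)))
  means <- matrix(means, nrow = length(blocks))
  colnames(means) <- vapply(normalTracks, sampleId, "")
  zero <- apply(means, 1L, function(x) any(is.na(x)))
  inRange <- !zero &
    apply(means, 1L, function(x) all(x >= low & x <= high))
  kept <- blocks[inRange]
  for (j in seq_len(ncol(means)))
    mcols(kept)[[paste0("mean_", colnames(means)[j])]] <-
      unname(means[inRange, j])
  dropped <- blocks[!inRange]
  excluded <- data.frame(chrom = as.character(seqnames(dropped)),
                         start = start(dropped), end = end(dropped),
                         reason = ifelse(zero[!inRange], "zero_coverage",
                                         "outside_range"))
  list(blocks = kept, excluded = excluded)
}

#' Allele-partitioned read-level ASM test
#'
#' For each region: keeps reads with an `allele_tag` of `ref`/`alt` and
#' at least `minCpgsPerRead` in-region calls, classifies them
#' ([classifyReads()]), drops undetermined reads, and requires at least
#' `minReadsPerAllele` classified reads per allele group. Evaluable
#' regions get a two-sided Fisher exact test on the
#' `[ref: (meth, unmeth); alt: (meth, unmeth)]` table; q-values are BH
#' over all evaluable regions of the call; `is_asm` iff `q < fdr`.
#'
#' @param reads a [MethReads-class] with allele tags.
#' @param regions [GenomicRanges::GRanges] of regions to test.
#' @param minReadsPerAllele minimum classified reads per allele group
#'   (default 8).
#' @param minCpgsPerRead minimum in-region CpG calls per read (default 4).
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame, one row per region: coordinates, the four table
#'   counts, `p`, `q`, `is_asm`, and `status` (`"tested"` or a skip
#'   reason).
#' @export
testAlleleASM <- function(reads, regions, minReadsPerAllele = 8L,
                          minCpgsPerRead = 4L, fdr = 0.05) {
  n <- length(regions)
  out <- data.frame(chrom = as.character(seqnames(regions)),
                    start = start(regions), end = end(regions),
                    ref_meth = NA_integer_, ref_unmeth = NA_integer_,
                    alt_meth = NA_integer_, alt_unmeth = NA_integer_,
                    p = NA_real_, q = NA_real_, is_asm = FALSE,
                    status = "skipped_no_tagged_reads")
  for (i in seq_len(n)) {
    cls <- classifyReads(reads, regions[i])
    cls <- cls[cls$allele_tag %in% c("ref", "alt") &
                 cls$n_calls >= minCpgsPerRead, , drop = FALSE]
    if (!nrow(cls)) next
    cls <- cls[cls$class != "undetermined", , drop = FALSE]
    tab <- table(factor(cls$allele_tag, c("ref", "alt")),
                 factor(cls$class, c("methylated", "unmethylated")))
    out$ref_meth[i] <- tab["ref", "methylated"]
    out$ref_unmeth[i] <- tab["ref", "unmethylated"]
    out$alt_meth[i] <- tab["alt", "methylated"]
    out$alt_unmeth[i] <- tab["alt", "unmethylated"]
    if (sum(tab["ref", ]) < minReadsPerAllele ||
        sum(tab["alt", ]) < minReadsPerAllele) {
      out$status[i] <- "skipped_min_reads"
      next
    }
    out$p[i] <- fisherPvalue(tab["ref", "methylated"],
                             tab["ref", "unmethylated"],
                             tab["alt", "methylated"],
                             tab["alt", "unmethylated"])
    out$status[i] <- "tested"
  }
  tested <- out$status == "tested"
  out$q[tested] <- bhAdjust(out$p[tested])
  out$is_asm <- tested & !is.na(out$q) & out$q < fdr
  out
}
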