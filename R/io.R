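## Readers/writers for the on-disk formats the pipeline touches, plus the
## interval algebra shared by every downstream module. All files are
## BED-family: tab-separated, 0-based half-open, LF-terminated, sorted.
## Internally everything is 1-based GRanges; conversion happens here only.

#' Read a bedmethyl CpG count table
#'
#' Parses the canonical 5-column bedmethyl dialect
#' (`chrom  start  end  meth_count  total_count`, 0-based half-open) into
#' a [MethTrack-class]. A 9+-column modkit-style dialect is accepted via
#' `dialect = "modkit"` (columns: chrom, start, end, name, score, strand,
#' ..., with `meth` and `total` taken from columns `modkitCols`).
#'
#' Forward/reverse-strand records of one CpG are collapsed onto the
#' forward-strand C by summing counts: with an explicit strand column,
#' `-` records are shifted to `pos - 1`; in the strandless 5-column
#' dialect a record immediately adjacent (+1) to the previous kept
#' position is treated as the reverse-strand mate (forward CpG starts are
#' always >= 2 bp apart).
#'
#' @param path file path.
#' @param sampleId sample identifier for the resulting track (default:
#'   file base name).
#' @param haplotype haplotype label to assign, one of
#'   `"combined"`, `"hap1"`, `"hap2"`.
#' @param dialect `"canonical"` (5 columns) or `"modkit"`.
#' @param modkitCols integer vector `c(meth, total)` column indices for
#'   the modkit dialect; defaults to the modkit pileup layout
#'   (valid coverage in column 10, N_mod in column 12).
#' @return a [MethTrack-class].
#' @export
readBedmethyl <- function(path, sampleId = NULL, haplotype = "combined",
                          dialect = c("canonical", "modkit"),
                          modkitCols = c(meth = 12L, total = 10L)) {
  dialect <- match.arg(dialect)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop("failed to parse '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (!nrow(df))
    return(MethTrack(sampleId, character(), integer(), integer(), integer(),
                     haplotype = haplotype))
  if (dialect == "canonical") {
    if (ncol(df) < 5L)
      stop("bedmethyl dialect needs >= 5 columns, got ", ncol(df))
    chrom <- as.character(df[[1L]]); start0 <- df[[2L]]
    meth <- df[[4L]]; total <- df[[5L]]
    strand <- if (ncol(df) >= 6L && all(df[[6L]] %in% c("+", "-", ".")))
      as.character(df[[6L]]) else NULL
  } else {
    if (ncol(df) < max(modkitCols))
      stop("modkit dialect needs >= ", max(modkitCols), " columns")
    chrom <- as.character(df[[1L]]); start0 <- df[[2L]]
    meth <- df[[modkitCols[["meth"]]]]
    total <- df[[modkitCols[["total"]]]]
    strand <- as.character(df[[6L]])
  }
  bad <- which(!is.finite(start0) | !is.finite(meth) | !is.finite(total))
  if (length(bad))
    stop("malformed bedmethyl line ", bad[1L], " in '", path, "'")
  if (any(meth < 0 | total < 0))
    stop("negative counts at line ", which(meth < 0 | total < 0)[1L],
         " in '", path, "'")
  if (any(meth > total))
    stop("meth_count exceeds total_count at line ",
         which(meth > total)[1L], " in '", path, "'")
  pos0 <- as.integer(start0)
  if (!is.null(strand)) {
    pos0[strand == "-"] <- pos0[strand == "-"] - 1L
  } else {
    o <- order(chrom, pos0)
    chrom <- chrom[o]; pos0 <- pos0[o]; meth <- meth[o]; total <- total[o]
    ## greedy left-to-right adjacency collapse (reverse-strand C sits at +1)
    keep <- pos0
    for (i in seq_along(pos0)[-1L]) {
      if (chrom[i] == chrom[i - 1L] && pos0[i] == keep[i - 1L] + 1L)
        keep[i] <- keep[i - 1L]
    }
    pos0 <- keep
  }
  key <- paste(chrom, pos0)
  meth <- tapply(meth, key, sum)
  total <- tapply(total, key, sum)
  meth <- meth[names(total)]
  parts <- strsplit(names(total), " ", fixed = TRUE)
  MethTrack(sampleId,
            chrom = vapply(parts, `[`, "", 1L),
            pos = as.integer(vapply(parts, `[`, "", 2L)),
            meth = as.integer(meth),
            unmeth = as.integer(total - meth),
            haplotype = haplotype, zeroBased = TRUE)
}

#' Write a MethTrack as canonical 5-column bedmethyl
#'
#' One line per (chrom, pos) in 0-based half-open coordinates; when the
#' track holds several haplotypes, `haplotype` selects which to emit.
#'
#' @param track a [MethTrack-class].
#' @param path output path.
#' @param haplotype which haplotype label to write (default `"combined"`).
#' @return `path`, invisibly.
#' @export
writeBedmethyl <- function(track, path, haplotype = "combined") {
  stopifnot(is(track, "MethTrack"))
  tr <- hapTrack(track, haplotype)
  gr <- cpgRanges(tr)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = start(gr),
                   meth = methCounts(tr),
                   total = totalCounts(tr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a per-read CpG call table
#'
#' TSV with header `read_id chrom pos call allele_tag hap_tag`; `pos` is
#' the 0-based position of the CpG's forward-strand C; `call` is `M` or
#' `U`. Missing tag columns default to `"none"`.
#'
#' @param path file path.
#' @param sampleId sample identifier (default: file base name).
#' @return a [MethReads-class]; an empty file yields zero reads.
#' @export
readReadTable <- function(path, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop("failed to parse '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (!nrow(df))
    return(MethReads(sampleId, data.frame(
      read_id = character(), chrom = character(), pos = integer(),
      call = character())))
  need <- c("read_id", "chrom", "pos", "call")
  if (!all(need %in% names(df)))
    stop("read table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$call %in% .CALLS))
    stop("unknown call symbol at line ",
         which(!(df$call %in% .CALLS))[1L], " in '", path, "'")
  if (anyDuplicated(paste(df$read_id, df$chrom, df$pos)))
    stop("duplicate (read_id, pos) call in '", path, "'")
  MethReads(sampleId, df, zeroBased = TRUE)
}

#' Write a MethReads object as the read-level TSV dialect
#'
#' @param reads a [MethReads-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReadTable <- function(reads, path) {
  stopifnot(is(reads, "MethReads"))
  df <- readCalls(reads)
  df$pos <- df$pos - 1L
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a BED3/BED4 interval set as GRanges
#'
#' Thin wrapper over [rtracklayer::import.bed]; the BED `name` column (if
#' present) is kept as metadata column `name`.
#'
#' @param path BED file path.
#' @return a [GenomicRanges::GRanges].
#' @export
readBedRanges <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr) <- mcols(gr)[, intersect("name", colnames(mcols(gr))),
                         drop = FALSE]
  gr
}

#' Write intervals as BED (BED4 when a `name` metadata column exists)
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedRanges <- function(gr, path) {
  gr <- sort(gr)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(mcols(gr)$name)) df$name <- mcols(gr)$name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Merge intervals with a gap and minimum-size rule
#'
#' Intervals separated by less than `maxGap` bases are merged; merged
#' intervals shorter than `minSize` bases are dropped. With the defaults
#' (`maxGap = 0`, `minSize = 0`) this is a plain overlap/abutment union.
#'
#' @param gr a [GenomicRanges::GRanges] (metadata columns are dropped).
#' @param maxGap merge intervals whose gap is strictly smaller than this
#'   many bases.
#' @param minSize drop merged intervals shorter than this many bases.
#' @return sorted, non-overlapping `GRanges`. Idempotent.
#' @examples
#' gr <- GenomicRanges::GRanges("chrS",
#'   IRanges::IRanges(c(1, 141), c(100, 200)))
#' mergeIntervals(gr, maxGap = 50)   # gap of 40 < 50 -> one interval
#' @export
mergeIntervals <- function(gr, maxGap = 0L, minSize = 0L) {
  stopifnot(maxGap >= 0L, minSize >= 0L)
  if (!length(gr)) return(GRanges())
  out <- reduce(granges(gr), min.gapwidth = max(1L, as.integer(maxGap)))
  out[width(out) >= minSize]
}

#' Multi-set interval intersection with per-segment counts
#'
#' Partitions the covered genome at every interval breakpoint of the
#' input sets and annotates each segment with the number of sets covering
#' it (a set covering a segment more than once counts once), the
#' `bedtools multiinter` semantics.
#'
#' @param sets a list of [GenomicRanges::GRanges] (or a `GRangesList`).
#' @return `GRanges` of disjoint segments with metadata column `count`
#'   (>= 1; uncovered genome is not reported).
#' @export
multiIntersect <- function(sets) {
  sets <- as.list(sets)
  stopifnot(length(sets) >= 1L)
  sets <- lapply(sets, function(g) reduce(granges(g)))
  all <- unlist(GRangesList(sets))
  if (!length(all)) return(GRanges(count = integer()))
  seg <- disjoin(all)
  cnt <- Reduce(`+`, lapply(sets, function(g)
    as.integer(countOverlaps(seg, g) > 0L)))
  mcols(seg)$count <- cnt
  sort(seg)
}
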