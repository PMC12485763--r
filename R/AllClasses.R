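#' @import methods
#' @importFrom stats fisher.test p.adjust cor quantile rbinom rpois runif sd
#' @importFrom utils read.table write.table
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits
#' @importFrom IRanges IRanges
#' @import GenomicRanges
NULL

.HAPLOTYPES <- c("combined", "hap1", "hap2")
.CALLS <- c("M", "U")

#' MethTrack: per-CpG methylation counts for one sample
#'
#' A `MethTrack` holds per-CpG methylated/unmethylated call counts for a
#' single sample, optionally split by haplotype. Each record is one CpG
#' (the forward-strand C, width-1 `GRanges` position, 1-based internally;
#' on-disk formats are 0-based half-open BED-family) with integer `meth`
#' and `unmeth` counts and a `haplotype` label (`combined`, `hap1`, or
#' `hap2`). Records are kept sorted by (chrom, pos, haplotype) and the
#' (chrom, pos, haplotype) key is unique.
#'
#' @slot sampleId single sample identifier.
#' @slot cpgs width-1 [GenomicRanges::GRanges] with metadata columns
#'   `haplotype`, `meth`, `unmeth`.
#'
#' @seealso [MethTrack()] for construction, [readBedmethyl()],
#'   [poolTracks()], [aggregateIntervals()]
#' @export
setClass("MethTrack", slots = c(sampleId = "character", cpgs = "GRanges"))

setValidity("MethTrack", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  mc <- mcols(object@cpgs)
  need <- c("haplotype", "meth", "unmeth")
  if (!all(need %in% colnames(mc))) {
    msg <- c(msg, "cpgs must carry metadata columns haplotype, meth, unmeth")
    return(if (length(msg)) msg else TRUE)
  }
  if (length(object@cpgs)) {
    if (!all(mc$haplotype %in% .HAPLOTYPES))
      msg <- c(msg, "haplotype must be one of combined/hap1/hap2")
    if (any(mc$meth < 0L) || any(mc$unmeth < 0L))
      msg <- c(msg, "negative methylation counts")
    if (!all(width(object@cpgs) == 1L))
      msg <- c(msg, "CpG records must have width 1")
    key <- paste(as.character(seqnames(object@cpgs)), start(object@cpgs),
                 mc$haplotype)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos, haplotype) records")
    o <- order(as.character(seqnames(object@cpgs)), start(object@cpgs),
               match(mc$haplotype, .HAPLOTYPES))
    if (!identical(o, seq_along(o)))
      msg <- c(msg, "records must be sorted by (chrom, pos, haplotype)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethTrack
#'
#' @param sampleId sample identifier.
#' @param chrom,pos chromosome names and CpG positions (positions of the
#'   forward-strand C). `pos` is interpreted as 1-based unless
#'   `zeroBased = TRUE`.
#' @param meth,unmeth non-negative integer call counts.
#' @param haplotype haplotype label(s), recycled; one of
#'   `"combined"`, `"hap1"`, `"hap2"`.
#' @param zeroBased set `TRUE` when `pos` follows the BED 0-based
#'   convention.
#' @return a [MethTrack-class] object, sorted and validated.
#' @examples
#' MethTrack("s1", chrom = "chrS", pos = c(101, 151),
#'           meth = c(5L, 3L), unmeth = c(5L, 7L))
#' @export
MethTrack <- function(sampleId, chrom, pos, meth, unmeth,
                      haplotype = "combined", zeroBased = FALSE) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n))
  if (zeroBased) pos <- pos + 1L
  gr <- GRanges(rep_len(as.character(chrom), n),
                IRanges(as.integer(pos), width = 1L))
  mcols(gr)$haplotype <- rep_len(as.character(haplotype), n)
  mcols(gr)$meth <- rep_len(as.integer(meth), n)
  mcols(gr)$unmeth <- rep_len(as.integer(unmeth), n)
  gr <- .sortTrackRanges(gr)
  new("MethTrack", sampleId = as.character(sampleId), cpgs = gr)
}

.sortTrackRanges <- function(gr) {
  o <- order(as.character(seqnames(gr)), start(gr),
             match(mcols(gr)$haplotype, .HAPLOTYPES))
  gr[o]
}

#' MethReads: per-read CpG methylation calls
#'
#' Container for per-molecule binary CpG methylation calls, the substrate
#' of read-level metrics, mLD, and allele-partitioned ASM testing. One row
#' per (read, CpG position); positions are 1-based internally. Each read
#' may carry an SNP allele tag (`ref`/`alt`/`none`) and a haplotype tag
#' (`hap1`/`hap2`/`none`).
#'
#' @slot sampleId sample identifier.
#' @slot calls data.frame with columns `read_id`, `chrom`, `pos`,
#'   `call` (`"M"`/`"U"`), `allele_tag`, `hap_tag`.
#' @export
setClass("MethReads", slots = c(sampleId = "character", calls = "data.frame"))

setValidity("MethReads", function(object) {
  msg <- character()
  df <- object@calls
  need <- c("read_id", "chrom", "pos", "call", "allele_tag", "hap_tag")
  if (!all(need %in% names(df)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$call %in% .CALLS))
      msg <- c(msg, "call symbols must be M or U")
    if (!all(df$allele_tag %in% c("ref", "alt", "none")))
      msg <- c(msg, "allele_tag must be ref/alt/none")
    if (!all(df$hap_tag %in% c("hap1", "hap2", "none")))
      msg <- c(msg, "hap_tag must be hap1/hap2/none")
    if (anyDuplicated(paste(df$read_id, df$chrom, df$pos)))
      msg <- c(msg, "duplicate (read_id, pos) call")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethReads object
#'
#' @param sampleId sample identifier.
#' @param calls data.frame with columns `read_id`, `chrom`, `pos` (1-based
#'   unless `zeroBased`), `call` in `"M"`/`"U"`; optional `allele_tag`,
#'   `hap_tag` (default `"none"`).
#' @param zeroBased positions follow the 0-based on-disk convention.
#' @return a [MethReads-class] object sorted by (read, chrom, pos).
#' @export
MethReads <- function(sampleId, calls, zeroBased = FALSE) {
  calls <- as.data.frame(calls)
  if (is.null(calls$allele_tag))
    calls$allele_tag <- rep("none", nrow(calls))
  if (is.null(calls$hap_tag))
    calls$hap_tag <- rep("none", nrow(calls))
  calls$read_id <- as.character(calls$read_id)
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- as.integer(calls$pos) + if (zeroBased) 1L else 0L
  calls$call <- as.character(calls$call)
  calls$allele_tag <- as.character(calls$allele_tag)
  calls$hap_tag <- as.character(calls$hap_tag)
  calls <- calls[order(calls$read_id, calls$chrom, calls$pos),
                 c("read_id", "chrom", "pos", "call", "allele_tag", "hap_tag"),
                 drop = FALSE]
  rownames(calls) <- NULL
  new("MethReads", sampleId = as.character(sampleId), calls = calls)
}

## ---- generics & accessors ---------------------------------------------

#' @describeIn MethTrack-class sample identifier
#' @param object,x a `MethTrack` or `MethReads`
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @export
setMethod("sampleId", "MethTrack", function(object) object@sampleId)

#' @export
setMethod("sampleId", "MethReads", function(object) object@sampleId)

#' @describeIn MethTrack-class the underlying width-1 GRanges of CpG records
#' @export
setGeneric("cpgRanges", function(object) standardGeneric("cpgRanges"))

#' @export
setMethod("cpgRanges", "MethTrack", function(object) object@cpgs)

#' @describeIn MethTrack-class methylated-call counts
#' @export
setGeneric("methCounts", function(object) standardGeneric("methCounts"))

#' @export
setMethod("methCounts", "MethTrack",
          function(object) mcols(object@cpgs)$meth)

#' @describeIn MethTrack-class unmethylated-call counts
#' @export
setGeneric("unmethCounts", function(object) standardGeneric("unmethCounts"))

#' @export
setMethod("unmethCounts", "MethTrack",
          function(object) mcols(object@cpgs)$unmeth)

#' @describeIn MethTrack-class total call counts (meth + unmeth)
#' @export
setGeneric("totalCounts", function(object) standardGeneric("totalCounts"))

#' @export
setMethod("totalCounts", "MethTrack",
          function(object) mcols(object@cpgs)$meth + mcols(object@cpgs)$unmeth)

#' @describeIn MethTrack-class per-CpG methylation fraction (NA at zero
#'   coverage)
#' @export
setGeneric("methFraction", function(object) standardGeneric("methFraction"))

#' @export
setMethod("methFraction", "MethTrack", function(object) {
  tot <- totalCounts(object)
  ifelse(tot > 0L, methCounts(object) / tot, NA_real_)
})

#' @describeIn MethTrack-class haplotype label of each record
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))

#' @export
setMethod("haplotypes", "MethTrack",
          function(object) mcols(object@cpgs)$haplotype)

#' Subset a track to one haplotype label
#'
#' @param track a [MethTrack-class]
#' @param haplotype one of `"combined"`, `"hap1"`, `"hap2"`
#' @return a `MethTrack` with only that haplotype's records.
#' @export
hapTrack <- function(track, haplotype) {
  stopifnot(is(track, "MethTrack"), haplotype %in% .HAPLOTYPES)
  new("MethTrack", sampleId = track@sampleId,
      cpgs = track@cpgs[mcols(track@cpgs)$haplotype == haplotype])
}

#' @export
setMethod("length", "MethTrack", function(x) length(x@cpgs))

setMethod("show", "MethTrack", function(object) {
  haps <- table(mcols(object@cpgs)$haplotype)
  cat("MethTrack '", object@sampleId, "': ", length(object@cpgs),
      " CpG records (",
      paste(names(haps), haps, sep = ":", collapse = ", "), ")\n", sep = "")
})

#' @describeIn MethReads-class per-call table (read_id, chrom, pos, call,
#'   allele_tag, hap_tag)
#' @export
setGeneric("readCalls", function(object) standardGeneric("readCalls"))

#' @export
setMethod("readCalls", "MethReads", function(object) object@calls)

#' @export
setMethod("length", "MethReads",
          function(x) length(unique(x@calls$read_id)))

setMethod("show", "MethReads", function(object) {
  cat("MethReads '", object@sampleId, "': ", length(object),
      " reads, ", nrow(object@calls), " CpG calls\n", sep = "")
})
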