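## End-to-end clonal pipeline and the `epimosaic` command-line
## dispatcher (a thin shell over the exported functions; see
## inst/exec/epimosaic.R).

#' Run the clonal analysis chain on synthetic data
#'
#' Chains the pipeline end to end: simulate a clone set, emit long reads
#' for block discovery, find methylation haplotype blocks (mLD r-squared
#' >= 0.5, >= 4 CpGs), select IMR blocks against the bulk normal, filter
#' confounded regions, call block-level ASM and epimutations per clone,
#' classify block states, and summarise switching and per-class
#' epimutation rates. Deterministic for a fixed config seed.
#'
#' @param config an [simConfig()] object.
#' @param outDir optional directory: when given, per-stage TSV/BED
#'   outputs are written (sorted, tab-separated).
#' @return list with `sim`, `blocks`, `imr` (IMR-selection result),
#'   `filter` (confounder-filter result), `asmCalls`, `epiCalls`,
#'   `states` (blocks x clones matrix), `switching`, `rates`.
#' @export
runClonalPipeline <- function(config = simConfig(), outDir = NULL) {
  sim <- simulateCloneSet(config)
  ## block discovery pools long reads across samples (multi-donor mLD)
  nPool <- min(4L, config$nClones)
  reads <- poolReads(lapply(seq_len(nPool), function(ci)
    emitReads(sim, mode = "long", clone = ci)))
  ld <- adjacentMLD(reads)
  blocks <- findBlocks(ld)
  imr <- selectIMRBlocks(blocks, list(sim$bulk))
  masks <- sim$truth$masks
  denseWin <- highSnpDensityWindows(masks$snps, masks$genome,
                                    window = config$snpWindow,
                                    topFraction = config$snpTopFraction)
  filt <- asmRegionFilter(imr$blocks, imprinted = masks$imprinted,
                          svBreakpoints = masks$svBreakpoints,
                          snpDenseWindows = denseWin)
  useBlocks <- filt$retained
  asmCalls <- lapply(sim$cloneTracks, function(tr)
    blockASMTest(useBlocks, tr))
  epiCalls <- lapply(sim$cloneTracks, function(tr)
    blockEpimutationTest(useBlocks, tr, sim$bulk))
  states <- cloneBlockMatrix(
    stats::setNames(lapply(seq_along(asmCalls), function(i)
      classifyBlockState(asmCalls[[i]], epiCalls[[i]])),
      vapply(sim$cloneTracks, sampleId, "")))
  switching <- switchingSummary(states)
  classes <- regionClassesFromTruth(sim$truth)
  rates <- regionClassEpimutationRates(
    classes, sim$cloneTracks[1L], sim$bulk)
  out <- list(sim = sim, blocks = blocks, imr = imr, filter = filt,
              asmCalls = asmCalls, epiCalls = epiCalls, states = states,
              switching = switching, rates = rates)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeBedRanges(blocks, file.path(outDir, "mhb_blocks.bed"))
    writeBedRanges(useBlocks, file.path(outDir, "imr_blocks.bed"))
    write.table(states, file.path(outDir, "block_states.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(data.frame(metric = names(switching)[1:4],
                           value = unlist(switching[1:4])),
                file.path(outDir, "switching.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(rates, file.path(outDir, "rates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Region classes derived from a simulation truth
#'
#' Maps planted block labels to the four region classes used for
#' per-class epimutation rates: random-ASM blocks are the IMR-block
#' class; constitutively unmethylated blocks stand in for CpG islands
#' and TSS (alternating); constitutively methylated blocks for
#' enhancers.
#'
#' @param truth `truth` element of a simulation result.
#' @return named list of [GenomicRanges::GRanges].
#' @export
regionClassesFromTruth <- function(truth) {
  b <- truth$blocks
  lab <- mcols(b)$label
  unmeth <- which(lab == "constitutive-unmethylated")
  list(IMR_blocks = granges(b[lab == "random-ASM"]),
       CpG_islands = granges(b[unmeth[seq_along(unmeth) %% 2L == 1L]]),
       TSS = granges(b[unmeth[seq_along(unmeth) %% 2L == 0L]]),
       enhancers = granges(b[lab == "constitutive-methylated"]))
}

## ---- CLI ---------------------------------------------------------------

.cliParse <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(pos = pos, opts = opts)
}

.cliOpt <- function(p, key, default = NULL, required = FALSE) {
  v <- p$opts[[key]]
  if (is.null(v)) {
    if (required) stop("missing required option --", key, call. = FALSE)
    return(default)
  }
  v
}

.cliWriteTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cliSimulate <- function(p) {
  preset <- .cliOpt(p, "preset", "clones")
  outDir <- .cliOpt(p, "out", required = TRUE)
  seed <- as.integer(.cliOpt(p, "seed", 1L))
  nBlocks <- as.integer(.cliOpt(p, "n-blocks", 200L))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "tissues") {
    panel <- simulateTissuePanel(seed = seed)
    for (ts in names(panel$tracks))
      for (tr in panel$tracks[[ts]])
        writeBedmethyl(tr, file.path(outDir,
                                     paste0(sampleId(tr), ".bedmethyl")))
    for (ts in names(panel$sampleBlockSets)) {
      sets <- panel$sampleBlockSets[[ts]]
      for (si in seq_along(sets))
        writeBedRanges(sets[[si]],
                       file.path(outDir,
                                 sprintf("%s_s%d.blocks.bed", ts, si)))
    }
    tb <- panel$truth
    mcols(tb)$name <- paste(mcols(tb)$label)
    writeBedRanges(tb, file.path(outDir, "truth_blocks.bed"))
    return(invisible(outDir))
  }
  cfg <- simConfig(nBlocks = nBlocks, seed = seed,
                   nNullBlocks = as.integer(.cliOpt(p, "n-null", 0L)))
  sim <- if (preset == "population") simulatePopulation(cfg)
         else simulateCloneSet(cfg)
  writeTrack <- function(tr) {
    base <- file.path(outDir, sampleId(tr))
    writeBedmethyl(tr, paste0(base, ".bedmethyl"))
    if (any(haplotypes(tr) == "hap1")) {
      writeBedmethyl(tr, paste0(base, ".hap1.bedmethyl"), "hap1")
      writeBedmethyl(tr, paste0(base, ".hap2.bedmethyl"), "hap2")
    }
  }
  writeTrack(sim$bulk)
  if (preset == "clones") {
    for (ci in seq_along(sim$cloneTracks)) {
      writeTrack(sim$cloneTracks[[ci]])
      writeReadTable(emitReads(sim, "long", clone = ci),
                     file.path(outDir,
                               sprintf("clone%02d.reads.tsv", ci)))
    }
  } else {
    writeReadTable(emitReads(sim, "long"),
                   file.path(outDir, "population.reads.tsv"))
    writeReadTable(emitReads(sim, "short"),
                   file.path(outDir, "population.frags.tsv"))
  }
  tb <- sim$truth$blocks
  mcols(tb)$name <- mcols(tb)$label
  writeBedRanges(tb, file.path(outDir, "truth_blocks.bed"))
  writeBedRanges(sim$truth$masks$imprinted,
                 file.path(outDir, "imprinted.bed"))
  writeBedRanges(sim$truth$masks$svBreakpoints,
                 file.path(outDir, "sv_breakpoints.bed"))
  writeBedRanges(sim$truth$masks$snps, file.path(outDir, "snps.bed"))
  writeLines(paste(names(sim$truth$masks$genome),
                   sim$truth$masks$genome, sep = "\t"),
             file.path(outDir, "genome.txt"))
  classes <- regionClassesFromTruth(sim$truth)
  for (cl in names(classes))
    writeBedRanges(classes[[cl]],
                   file.path(outDir, paste0("class_", cl, ".bed")))
  invisible(outDir)
}

.cliReadGenome <- function(path) {
  df <- read.table(path, sep = "\t")
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

.cliHapTrackFromFiles <- function(hap1Path, hap2Path, sampleIdStr) {
  h1 <- readBedmethyl(hap1Path, sampleIdStr, haplotype = "hap1")
  h2 <- readBedmethyl(hap2Path, sampleIdStr, haplotype = "hap2")
  g1 <- cpgRanges(h1); g2 <- cpgRanges(h2)
  MethTrack(sampleIdStr,
            chrom = c(as.character(seqnames(g1)),
                      as.character(seqnames(g2))),
            pos = c(start(g1), start(g2)),
            meth = c(methCounts(h1), methCounts(h2)),
            unmeth = c(unmethCounts(h1), unmethCounts(h2)),
            haplotype = rep(c("hap1", "hap2"), c(length(g1), length(g2))))
}

#' epimosaic command-line entry point
#'
#' Dispatches the subcommands exposed by the `epimosaic` Rscript
#' (`inst/exec/epimosaic.R`): `simulate`, `convert`, `merge`,
#' `intersect`, `aggregate`, `dmr`, `hotspots`, `metrics`, `asm-wgbs`,
#' `blocks`, `asm-ont`, `epimutation`, `switching`, `concordance`,
#' `rates`. Each is a thin file-in/file-out wrapper over the
#' corresponding exported function.
#'
#' @param args character vector of command-line arguments
#'   (subcommand first).
#' @return invisibly, the main output path or object of the subcommand.
#' @export
epimosaicMain <- function(args) {
  if (!length(args)) stop("usage: epimosaic <command> [--opt value ...]")
  cmd <- args[1L]
  p <- .cliParse(args[-1L])
  switch(cmd,
    simulate = .cliSimulate(p),
    convert = {
      tr <- readBedmethyl(.cliOpt(p, "in", required = TRUE),
                          dialect = .cliOpt(p, "dialect", "modkit"))
      writeBedmethyl(tr, .cliOpt(p, "out", required = TRUE))
    },
    merge = {
      gr <- readBedRanges(.cliOpt(p, "in", required = TRUE))
      out <- mergeIntervals(gr,
                            maxGap = as.integer(.cliOpt(p, "max-gap", 0L)),
                            minSize = as.integer(.cliOpt(p, "min-size", 0L)))
      writeBedRanges(out, .cliOpt(p, "out", required = TRUE))
    },
    intersect = {
      paths <- strsplit(.cliOpt(p, "in", required = TRUE), ",")[[1L]]
      seg <- multiIntersect(lapply(paths, readBedRanges))
      .cliWriteTsv(data.frame(chrom = as.character(seqnames(seg)),
                              start = start(seg) - 1L, end = end(seg),
                              count = mcols(seg)$count),
                   .cliOpt(p, "out", required = TRUE))
    },
    aggregate = {
      tr <- readBedmethyl(.cliOpt(p, "track", required = TRUE))
      rg <- readBedRanges(.cliOpt(p, "regions", required = TRUE))
      .cliWriteTsv(aggregateIntervals(tr, rg),
                   .cliOpt(p, "out", required = TRUE))
    },
    dmr = {
      s <- readBedmethyl(.cliOpt(p, "sample", required = TRUE))
      r <- readBedmethyl(.cliOpt(p, "reference", required = TRUE))
      .cliWriteTsv(callDMRs(s, r,
                            minDiff = as.numeric(.cliOpt(p, "min-diff",
                                                         0.3))),
                   .cliOpt(p, "out", required = TRUE))
    },
    hotspots = {
      paths <- strsplit(.cliOpt(p, "dmrs", required = TRUE), ",")[[1L]]
      sets <- lapply(paths, function(f) {
        df <- read.table(f, sep = "\t", header = TRUE)
        dmrRanges(df)
      })
      track <- if (!is.null(p$opts$track))
        readBedmethyl(.cliOpt(p, "track")) else NULL
      hot <- findHotspots(sets,
                          minRecurrence = as.integer(.cliOpt(p,
                            "min-recurrence", 25L)),
                          minCpgs = as.integer(.cliOpt(p, "min-cpgs", 5L)),
                          track = track)
      .cliWriteTsv(data.frame(chrom = as.character(seqnames(hot)),
                              start = start(hot) - 1L, end = end(hot),
                              recurrence = mcols(hot)$recurrence,
                              n_cpgs = mcols(hot)$n_cpgs),
                   .cliOpt(p, "out", required = TRUE))
    },
    metrics = {
      reads <- readReadTable(.cliOpt(p, "reads", required = TRUE))
      rg <- readBedRanges(.cliOpt(p, "regions", required = TRUE))
      rows <- do.call(rbind, lapply(seq_along(rg), function(i)
        cbind(data.frame(chrom = as.character(seqnames(rg))[i],
                         start = start(rg)[i] - 1L, end = end(rg)[i]),
              fragmentMetrics(reads, rg[i]))))
      .cliWriteTsv(rows, .cliOpt(p, "out", required = TRUE))
    },
    `asm-wgbs` = {
      reads <- readReadTable(.cliOpt(p, "reads", required = TRUE))
      rg <- readBedRanges(.cliOpt(p, "regions", required = TRUE))
      .cliWriteTsv(testAlleleASM(reads, rg),
                   .cliOpt(p, "out", required = TRUE))
    },
    blocks = {
      reads <- readReadTable(.cliOpt(p, "reads", required = TRUE))
      ld <- adjacentMLD(reads,
                        minPairReads = as.integer(.cliOpt(p,
                          "min-pair-reads", 10L)))
      bl <- findBlocks(ld,
                       r2Threshold = as.numeric(.cliOpt(p, "r2", 0.5)),
                       minCpgs = as.integer(.cliOpt(p, "min-cpgs", 4L)))
      writeBedRanges(bl, .cliOpt(p, "out", required = TRUE))
      if (!is.null(p$opts$pairs)) .cliWriteTsv(ld, p$opts$pairs)
      invisible(bl)
    },
    `asm-ont` = {
      tr <- .cliHapTrackFromFiles(.cliOpt(p, "hap1", required = TRUE),
                                  .cliOpt(p, "hap2", required = TRUE),
                                  .cliOpt(p, "sample-id", "sample"))
      bl <- readBedRanges(.cliOpt(p, "blocks", required = TRUE))
      .cliWriteTsv(blockASMTest(bl, tr),
                   .cliOpt(p, "out", required = TRUE))
    },
    epimutation = {
      s <- readBedmethyl(.cliOpt(p, "sample", required = TRUE))
      r <- readBedmethyl(.cliOpt(p, "normal", required = TRUE))
      bl <- readBedRanges(.cliOpt(p, "blocks", required = TRUE))
      .cliWriteTsv(blockEpimutationTest(bl, s, r),
                   .cliOpt(p, "out", required = TRUE))
    },
    switching = {
      m <- as.matrix(read.table(.cliOpt(p, "states", required = TRUE),
                                sep = "\t", header = TRUE,
                                row.names = 1L, check.names = FALSE))
      sw <- switchingSummary(m,
                             minAsmSamples = as.integer(.cliOpt(p,
                               "min-asm-samples", 4L)))
      .cliWriteTsv(data.frame(metric = names(sw)[1:4],
                              value = unlist(sw[1:4])),
                   .cliOpt(p, "out", required = TRUE))
    },
    concordance = {
      t1 <- read.table(.cliOpt(p, "t1", required = TRUE), sep = "\t",
                       header = TRUE)
      t2 <- read.table(.cliOpt(p, "t2", required = TRUE), sep = "\t",
                       header = TRUE)
      res <- timepointConcordance(t1$state, t2$state,
                                  category = .cliOpt(p, "category",
                                                     "ASM"))
      .cliWriteTsv(data.frame(metric = names(res),
                              value = unlist(res)),
                   .cliOpt(p, "out", required = TRUE))
    },
    rates = {
      paths <- strsplit(.cliOpt(p, "classes", required = TRUE),
                        ",")[[1L]]
      classes <- lapply(paths, readBedRanges)
      names(classes) <- sub("\\.bed$", "",
                            sub("^class_", "", basename(paths)))
      tumor <- readBedmethyl(.cliOpt(p, "tumor", required = TRUE))
      normal <- readBedmethyl(.cliOpt(p, "normal", required = TRUE))
      .cliWriteTsv(regionClassEpimutationRates(classes, list(tumor),
                                               normal),
                   .cliOpt(p, "out", required = TRUE))
    },
    stop("unknown command: ", cmd)
  )
}
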