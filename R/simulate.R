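## Synthetic clonal methylation data with planted ground truth.
##
## The generator emulates the generative hypothesis the callers are built
## for: discrete blocks of correlated CpGs at which each cell randomly
## methylates one haplotype (random ASM), against a background of
## constitutively methylated/unmethylated blocks, with planted
## epimutations in clones and planted confounders (imprinted blocks,
## SV-adjacent artifacts, SNP-dense windows, chrX blocks). All
## randomness is seeded through the config; the same seed gives
## byte-identical output.

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the test
#' suite: blocks of a mean of 12 CpGs spanning ~186 bp on a 10 Mb
#' synthetic contig `chrS` (plus a 1 Mb `chrX` decoy), a per-cell
#' random-ASM haplotype choice with probability `asmProb`, per-call
#' error `errorRate`, and Poisson read coverage.
#'
#' @param nBlocks number of non-confounder blocks.
#' @param cpgsPerBlock mean CpGs per block (truncated to
#'   `[minCpgsPerBlock, maxCpgsPerBlock]`).
#' @param minCpgsPerBlock,maxCpgsPerBlock block-size truncation (4, 20).
#' @param blockSpanBp mean block span in bases.
#' @param nCells cells in a polyclonal population.
#' @param nClones single-cell-derived clones.
#' @param asmProb probability a cell/clone methylates haplotype 1 at a
#'   random-ASM block.
#' @param epimutationRate per-clone, per-block probability that a
#'   random-ASM block carries a both-haplotype epimutation instead.
#' @param epiHyperBias fraction of epimutated blocks that are
#'   hypermethylated (default 0.7; clone epimutations skew hyper).
#' @param errorRate per-call error epsilon in `[0, 1]` (default 0.02).
#' @param meanCoverage mean read coverage of a clone/sample track (reads
#'   per CpG, both haplotypes together).
#' @param cellCoverage per-cell, per-haplotype CpG coverage used for the
#'   population bulk track (bulk counts are the exact sum over cells).
#' @param fracRandomAsm,fracConstM,fracConstU composition of the
#'   non-confounder blocks (random-ASM, constitutively methylated,
#'   constitutively unmethylated); must sum to 1.
#' @param nImprinted,nSvAdjacent,nSnpDense,nChrX planted confounder
#'   block counts.
#' @param nNullBlocks regions whose reads carry independent fair-coin
#'   calls (mLD independence null).
#' @param fragCpgSpan mean CpGs spanned by a short-read fragment
#'   (minimum 4).
#' @param chrSLength,chrXLength contig lengths.
#' @param snpWindow,snpTopFraction SNP-density window size / masked top
#'   fraction (10 kb, 1 percent); dense windows are planted so that the
#'   top-1-percent rule has a defined truth.
#' @param denseSnpCount,baselineSnpRate SNPs per dense window; mean
#'   baseline SNPs per window.
#' @param seed RNG seed; identical seed implies identical output.
#' @return a validated `epimosaic_config` list.
#' @export
simConfig <- function(nBlocks = 200L, cpgsPerBlock = 12,
                      minCpgsPerBlock = 4L, maxCpgsPerBlock = 20L,
                      blockSpanBp = 186, nCells = 10000L, nClones = 11L,
                      asmProb = 0.5, epimutationRate = 0.05,
                      epiHyperBias = 0.7, errorRate = 0.02,
                      meanCoverage = 30, cellCoverage = 2,
                      fracRandomAsm = 0.8, fracConstM = 0.1,
                      fracConstU = 0.1, nImprinted = 5L,
                      nSvAdjacent = 5L, nSnpDense = 5L, nChrX = 5L,
                      nNullBlocks = 0L, fragCpgSpan = 6,
                      chrSLength = 10000000L, chrXLength = 1000000L,
                      snpWindow = 10000L, snpTopFraction = 0.01,
                      denseSnpCount = 50L, baselineSnpRate = 1,
                      seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(asmProb, epimutationRate, epiHyperBias, errorRate,
             fracRandomAsm, fracConstM, fracConstU, snpTopFraction)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]")
  if (abs(fracRandomAsm + fracConstM + fracConstU - 1) > 1e-9)
    stop("config error: block composition fractions must sum to 1")
  counts <- c(nBlocks, nCells, nClones, nImprinted, nSvAdjacent,
              nSnpDense, nChrX, nNullBlocks)
  if (any(counts < 0)) stop("config error: counts must be >= 0")
  if (nClones < 1L) stop("config error: nClones must be >= 1")
  structure(cfg, class = "epimosaic_config")
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

## block geometry + labels; deterministic given the RNG state
.simLayout <- function(cfg) {
  labels <- c(rep("random-ASM", round(cfg$fracRandomAsm * cfg$nBlocks)),
              rep("constitutive-methylated",
                  round(cfg$fracConstM * cfg$nBlocks)))
  labels <- c(labels, rep("constitutive-unmethylated",
                          cfg$nBlocks - length(labels)))
  labels <- sample(labels)
  labels <- c(labels, rep("imprinted", cfg$nImprinted),
              rep("SV-adjacent", cfg$nSvAdjacent),
              rep("SNP-dense", cfg$nSnpDense),
              rep("null-independent", cfg$nNullBlocks))
  labels <- sample(labels)                      # interleave along chrS
  labels <- c(labels, rep("chrX", cfg$nChrX))   # decoy contig last
  n <- length(labels)
  chrom <- c(rep("chrS", n - cfg$nChrX), rep("chrX", cfg$nChrX))
  nCpg <- pmin(pmax(rpois(n, cfg$cpgsPerBlock), cfg$minCpgsPerBlock),
               cfg$maxCpgsPerBlock)
  cpgPos <- vector("list", n)
  cursor <- c(chrS = 10000L, chrX = 10000L)
  ## SNP-dense blocks are kept in isolated density windows (extra gap on
  ## both sides) so that masking their window cannot catch a neighbour
  iso <- as.integer(cfg$snpWindow + 2000L)
  for (i in seq_len(n)) {
    if (labels[i] == "SNP-dense")
      cursor[[chrom[i]]] <- cursor[[chrom[i]]] + iso
    span <- max(2L * nCpg[i],
                as.integer(round(cfg$blockSpanBp * runif(1, 0.7, 1.3))))
    step <- diff(round(seq(0, span, length.out = nCpg[i])))
    step <- pmax(step + sample(-1:1, nCpg[i] - 1L, replace = TRUE), 2L)
    pos <- cursor[[chrom[i]]] + c(0L, cumsum(step))
    cpgPos[[i]] <- as.integer(pos)
    gap <- as.integer(round(runif(1, 2000, 4000)))
    if (labels[i] == "SNP-dense") gap <- gap + iso
    cursor[[chrom[i]]] <- pos[length(pos)] + gap
  }
  if (cursor[["chrS"]] > 0.85 * cfg$chrSLength ||
      cursor[["chrX"]] > 0.85 * cfg$chrXLength)
    stop("config error: block layout exceeds the synthetic contigs; ",
         "reduce nBlocks or enlarge the genome")
  blocks <- GRanges(chrom, IRanges(vapply(cpgPos, min, 1L),
                                   vapply(cpgPos, max, 1L)))
  mcols(blocks)$block_id <- sprintf("b%04d", seq_len(n))
  mcols(blocks)$label <- labels
  mcols(blocks)$n_cpgs <- nCpg
  mcols(blocks)$cpg_pos <- IRanges::IntegerList(cpgPos)
  mcols(blocks)$snp_pos <- as.integer(round((start(blocks) +
                                               end(blocks)) / 2))
  blocks
}

## masks + SNP field around a layout
.simMasks <- function(cfg, blocks) {
  lab <- mcols(blocks)$label
  genome <- c(chrS = cfg$chrSLength, chrX = cfg$chrXLength)
  imprinted <- granges(blocks[lab == "imprinted"])
  ## SV breakpoints: one within 1 kb of each SV-adjacent block, plus a
  ## few decoys far (> 2.5 kb) from every block
  svNear <- blocks[lab == "SV-adjacent"]
  svPos <- end(svNear) + as.integer(round(runif(length(svNear), 100, 900)))
  svFar <- as.integer(round(runif(3, 0.90, 0.99) * cfg$chrSLength))
  sv <- GRanges(rep("chrS", length(svPos) + length(svFar)),
                IRanges(c(svPos, svFar), width = 1L))
  ## SNPs: Poisson baseline per 10 kb window; planted dense windows are
  ## exactly the top fraction of all windows so the density mask has a
  ## defined planted truth
  tiles <- GenomicRanges::tileGenome(genome, tilewidth = cfg$snpWindow,
                                     cut.last.tile.in.chrom = TRUE)
  nWin <- length(tiles)
  nDense <- as.integer(ceiling(cfg$snpTopFraction * nWin))
  denseIdx <- unique(queryHits(findOverlaps(tiles,
                                            blocks[lab == "SNP-dense"])))
  offLimits <- unique(queryHits(findOverlaps(tiles, blocks,
                                             maxgap = cfg$snpWindow)))
  pool <- setdiff(seq_len(nWin), offLimits)
  extra <- sample(pool, max(0L, nDense - length(denseIdx)))
  denseIdx <- c(denseIdx, extra)
  nSnp <- rpois(nWin, cfg$baselineSnpRate)
  nSnp[denseIdx] <- cfg$denseSnpCount
  snpPos <- lapply(seq_len(nWin), function(i) {
    if (nSnp[i] == 0L) return(integer())
    sort(unique(as.integer(start(tiles)[i] +
                             floor(runif(nSnp[i]) * width(tiles)[i]))))
  })
  snps <- GRanges(rep(as.character(seqnames(tiles)), lengths(snpPos)),
                  IRanges(unlist(snpPos), width = 1L))
  list(genome = genome, imprinted = imprinted, svBreakpoints = sv,
       snps = snps, denseWindows = granges(tiles[denseIdx]))
}

## per-CpG counts for one haplotype of one block given the fraction of
## cells methylating it; exact sum over cells via Poisson thinning
.popHapCounts <- function(nCpg, nMethCells, nCells, cellCov, eps) {
  nM <- rpois(nCpg, nMethCells * cellCov)
  nU <- rpois(nCpg, (nCells - nMethCells) * cellCov)
  meth <- rbinom(nCpg, nM, 1 - eps) + rbinom(nCpg, nU, eps)
  cbind(meth = meth, total = nM + nU)
}

.trackFromBlockCounts <- function(sampleIdStr, blocks, counts) {
  ## counts: list per block of list(hap1 = cbind(meth,total), hap2 = ...)
  chrom <- rep(as.character(seqnames(blocks)),
               mcols(blocks)$n_cpgs)
  pos <- unlist(as.list(mcols(blocks)$cpg_pos), use.names = FALSE)
  m1 <- unlist(lapply(counts, function(x) x$hap1[, "meth"]))
  t1 <- unlist(lapply(counts, function(x) x$hap1[, "total"]))
  m2 <- unlist(lapply(counts, function(x) x$hap2[, "meth"]))
  t2 <- unlist(lapply(counts, function(x) x$hap2[, "total"]))
  MethTrack(sampleIdStr,
            chrom = c(chrom, chrom, chrom),
            pos = c(pos, pos, pos),
            meth = c(m1 + m2, m1, m2),
            unmeth = c((t1 + t2) - (m1 + m2), t1 - m1, t2 - m2),
            haplotype = rep(c("combined", "hap1", "hap2"),
                            each = length(pos)))
}

## haplotype methylation state of every cell for one block
.cellStates <- function(label, nCells, asmProb) {
  switch(label,
    "random-ASM" = , "SV-adjacent" = , "SNP-dense" = , "chrX" = {
      h1 <- runif(nCells) < asmProb
      cbind(h1 = h1, h2 = !h1)
    },
    "constitutive-methylated" = cbind(h1 = rep(TRUE, nCells),
                                      h2 = rep(TRUE, nCells)),
    "constitutive-unmethylated" = cbind(h1 = rep(FALSE, nCells),
                                        h2 = rep(FALSE, nCells)),
    "imprinted" = cbind(h1 = rep(TRUE, nCells),
                        h2 = rep(FALSE, nCells)),
    "null-independent" = NULL)   # no cell-level structure
}

#' Simulate a polyclonal cell population
#'
#' Each cell independently methylates haplotype 1 of every random-ASM
#' block with probability `asmProb` (haplotype 2 otherwise); the bulk
#' track is the count sum over all cells (per-cell, per-haplotype CpG
#' coverage `cellCoverage`, per-call error `errorRate`). Confounder
#' blocks behave per their labels: imprinted blocks have a fixed
#' parental-style haplotype in every cell, SV-adjacent/SNP-dense/chrX
#' blocks are random-ASM lookalikes that only the masks distinguish,
#' and null-independent blocks have per-call fair-coin methylation.
#'
#' @param config an [simConfig()] object.
#' @param perCell materialise per-cell tracks (requires a small
#'   `nCells`); the bulk track is then the exact per-cell sum.
#' @return list: `bulk` (a [MethTrack-class] with combined/hap1/hap2
#'   records), `truth` (blocks `GRanges` with labels and per-block
#'   hap1-methylating cell counts, masks, genome, config), and with
#'   `perCell = TRUE` also `cellTracks`.
#' @export
simulatePopulation <- function(config = simConfig(), perCell = FALSE) {
  stopifnot(inherits(config, "epimosaic_config"))
  if (perCell && config$nCells > 200L)
    stop("perCell mode is for small nCells")
  .withSeed(config$seed, {
    blocks <- .simLayout(config)
    masks <- .simMasks(config, blocks)
    lab <- mcols(blocks)$label
    nCpg <- mcols(blocks)$n_cpgs
    eps <- config$errorRate
    nMeth1 <- integer(length(blocks))
    cellTracks <- NULL
    if (!perCell) {
      counts <- vector("list", length(blocks))
      for (i in seq_along(blocks)) {
        if (lab[i] == "null-independent") {
          tot <- config$nCells * config$cellCoverage
          n1 <- rpois(nCpg[i], tot); n2 <- rpois(nCpg[i], tot)
          counts[[i]] <- list(
            hap1 = cbind(meth = rbinom(nCpg[i], n1, 0.5), total = n1),
            hap2 = cbind(meth = rbinom(nCpg[i], n2, 0.5), total = n2))
          nMeth1[i] <- NA_integer_
          next
        }
        st <- .cellStates(lab[i], config$nCells, config$asmProb)
        k1 <- sum(st[, "h1"]); k2 <- sum(st[, "h2"])
        nMeth1[i] <- k1
        counts[[i]] <- list(
          hap1 = .popHapCounts(nCpg[i], k1, config$nCells,
                               config$cellCoverage, eps),
          hap2 = .popHapCounts(nCpg[i], k2, config$nCells,
                               config$cellCoverage, eps))
      }
      bulk <- .trackFromBlockCounts("bulk_normal", blocks, counts)
    } else {
      ## explicit per-cell counts; bulk = exact column sum
      perCellCounts <- lapply(seq_len(config$nCells), function(ci)
        vector("list", length(blocks)))
      stateList <- lapply(seq_along(blocks), function(i)
        .cellStates(lab[i], config$nCells, config$asmProb))
      for (i in seq_along(blocks)) {
        st <- stateList[[i]]
        if (!is.null(st)) nMeth1[i] <- sum(st[, "h1"])
        else nMeth1[i] <- NA_integer_
        for (ci in seq_len(config$nCells)) {
          drawHap <- function(methylated) {
            n <- rpois(nCpg[i], config$cellCoverage)
            p <- if (is.na(methylated)) 0.5
                 else if (methylated) 1 - eps else eps
            cbind(meth = rbinom(nCpg[i], n, p), total = n)
          }
          perCellCounts[[ci]][[i]] <- list(
            hap1 = drawHap(if (is.null(st)) NA else st[ci, "h1"]),
            hap2 = drawHap(if (is.null(st)) NA else st[ci, "h2"]))
        }
      }
      cellTracks <- lapply(seq_len(config$nCells), function(ci)
        .trackFromBlockCounts(sprintf("cell%03d", ci), blocks,
                              perCellCounts[[ci]]))
      sumCounts <- lapply(seq_along(blocks), function(i) {
        add <- function(hap) Reduce(`+`, lapply(perCellCounts,
                                                function(pc) pc[[i]][[hap]]))
        list(hap1 = add("hap1"), hap2 = add("hap2"))
      })
      bulk <- .trackFromBlockCounts("bulk_normal", blocks, sumCounts)
    }
    mcols(blocks)$n_hap1_meth_cells <- nMeth1
    truth <- list(blocks = blocks, masks = masks, config = config)
    out <- list(bulk = bulk, truth = truth)
    if (perCell) out$cellTracks <- cellTracks
    out
  })
}

#' Simulate single-cell-derived clones plus a bulk population
#'
#' Each clone independently draws, per random-ASM block, either a
#' methylated haplotype (probability `1 - epimutationRate`, haplotype 1
#' with probability `asmProb`) or a both-haplotype epimutation
#' (hypermethylated with probability `epiHyperBias`). Clone tracks are
#' sequenced at `meanCoverage` (split across haplotypes); the bulk track
#' is an independent polyclonal population on the same block layout.
#'
#' @param config an [simConfig()] object.
#' @return list: `cloneTracks` (list of [MethTrack-class]), `bulk`,
#'   `truth` (as in [simulatePopulation()], plus `cloneStates`, a
#'   blocks x clones character matrix over
#'   `{hap1, hap2, hyper, hypo, M, U, imprinted-hap1, null}`).
#' @export
simulateCloneSet <- function(config = simConfig()) {
  stopifnot(inherits(config, "epimosaic_config"))
  pop <- simulatePopulation(config)
  blocks <- pop$truth$blocks
  lab <- mcols(blocks)$label
  nCpg <- mcols(blocks)$n_cpgs
  eps <- config$errorRate
  .withSeed(config$seed + 1000003L, {
    states <- matrix("", nrow = length(blocks), ncol = config$nClones,
                     dimnames = list(mcols(blocks)$block_id,
                                     sprintf("clone%02d", seq_len(config$nClones))))
    for (i in seq_along(blocks)) {
      states[i, ] <- switch(lab[i],
        "constitutive-methylated" = "M",
        "constitutive-unmethylated" = "U",
        "imprinted" = "imprinted-hap1",
        "null-independent" = "null",
        ## random-ASM and its confounder lookalikes
        {
          epi <- runif(config$nClones) < config$epimutationRate
          hapPick <- ifelse(runif(config$nClones) < config$asmProb,
                            "hap1", "hap2")
          epiPick <- ifelse(runif(config$nClones) < config$epiHyperBias,
                            "hyper", "hypo")
          ifelse(epi, epiPick, hapPick)
        })
    }
    covHap <- config$meanCoverage / 2
    hapP <- function(state, hap) {
      methylated <- switch(state,
        hap1 = hap == "hap1", hap2 = hap == "hap2",
        hyper = TRUE, hypo = FALSE, M = TRUE, U = FALSE,
        `imprinted-hap1` = hap == "hap1", null = NA)
      if (is.na(methylated)) 0.5 else if (methylated) 1 - eps else eps
    }
    cloneTracks <- lapply(seq_len(config$nClones), function(ci) {
      counts <- lapply(seq_along(blocks), function(i) {
        draw <- function(hap) {
          n <- rpois(nCpg[i], covHap)
          cbind(meth = rbinom(nCpg[i], n, hapP(states[i, ci], hap)),
                total = n)
        }
        list(hap1 = draw("hap1"), hap2 = draw("hap2"))
      })
      .trackFromBlockCounts(sprintf("clone%02d", ci), blocks, counts)
    })
    truth <- pop$truth
    truth$cloneStates <- states
    list(cloneTracks = cloneTracks, bulk = pop$bulk, truth = truth)
  })
}

#' Emit per-read CpG calls from a simulation
#'
#' Long mode emits haplotype-tagged reads spanning whole blocks (per-CpG
#' depth is Poisson with mean `meanCoverage`, split evenly across
#' haplotypes); short mode emits fragments spanning at least 4 CpGs
#' whose reads carry an `allele_tag` (haplotype 1 = `ref`) whenever the
#' fragment overlaps the block's planted SNP. Per-call flip probability
#' is `errorRate`.
#'
#' @param sim result of [simulatePopulation()] or [simulateCloneSet()].
#' @param mode `"long"` or `"short"`.
#' @param clone clone index for clone simulations; `NULL` samples cells
#'   from the polyclonal population.
#' @param sampleId identifier for the returned [MethReads-class].
#' @return a [MethReads-class].
#' @export
emitReads <- function(sim, mode = c("long", "short"), clone = NULL,
                      sampleId = NULL) {
  mode <- match.arg(mode)
  truth <- sim$truth
  cfg <- truth$config
  blocks <- truth$blocks
  lab <- mcols(blocks)$label
  if (is.null(sampleId))
    sampleId <- if (is.null(clone)) paste0("population_", mode)
                else sprintf("clone%02d_%s", clone, mode)
  seedOff <- 2000003L + (if (is.null(clone)) 0L else clone) +
    (if (mode == "short") 500L else 0L)
  .withSeed(cfg$seed + seedOff, {
    eps <- cfg$errorRate
    rows <- vector("list", length(blocks))
    ridBase <- 0L
    for (i in seq_along(blocks)) {
      pos <- mcols(blocks)$cpg_pos[[i]]
      L <- length(pos)
      ch <- as.character(seqnames(blocks))[i]
      ## probability that a read on `hap` is from a methylating cell
      pMethRead <- function(hap) {
        if (lab[i] == "null-independent") return(NA_real_)
        if (!is.null(clone)) {
          st <- truth$cloneStates[i, clone]
          m <- switch(st, hap1 = hap == "hap1", hap2 = hap == "hap2",
                      hyper = TRUE, hypo = FALSE, M = TRUE, U = FALSE,
                      `imprinted-hap1` = hap == "hap1", null = NA)
          if (is.na(m)) return(NA_real_)
          return(if (m) 1 else 0)
        }
        k1 <- mcols(blocks)$n_hap1_meth_cells[i]
        if (is.na(k1)) return(NA_real_)
        f1 <- k1 / cfg$nCells
        switch(lab[i],
          "constitutive-methylated" = 1,
          "constitutive-unmethylated" = 0,
          "imprinted" = if (hap == "hap1") 1 else 0,
          if (hap == "hap1") f1 else 1 - f1)   # random-ASM style
      }
      emitHap <- function(hap, nReads, span = NULL) {
        if (nReads == 0L) return(NULL)
        pm <- pMethRead(hap)
        rid <- sprintf("%s_%s_r%06d", sampleId,
                       mcols(blocks)$block_id[i],
                       ridBase + seq_len(nReads))
        ridBase <<- ridBase + nReads
        perRead <- lapply(seq_len(nReads), function(r) {
          idx <- if (is.null(span)) seq_len(L) else span[[r]]
          pMeth <- if (is.na(pm)) 0.5
                   else if (runif(1) < pm) 1 - eps else eps
          calls <- ifelse(runif(length(idx)) < pMeth, "M", "U")
          data.frame(read_id = rid[r], chrom = ch, pos = pos[idx],
                     call = calls)
        })
        df <- do.call(rbind, perRead)
        df$hap_tag <- if (mode == "long") hap else "none"
        if (mode == "short") {
          snp <- mcols(blocks)$snp_pos[i]
          covers <- vapply(perRead, function(d)
            min(d$pos) <= snp && max(d$pos) >= snp, TRUE)
          df$allele_tag <- rep(ifelse(covers,
                                      if (hap == "hap1") "ref" else "alt",
                                      "none"),
                               vapply(perRead, nrow, 1L))
        } else df$allele_tag <- "none"
        df
      }
      if (mode == "long") {
        n1 <- rpois(1, cfg$meanCoverage / 2)
        n2 <- rpois(1, cfg$meanCoverage / 2)
        rows[[i]] <- rbind(emitHap("hap1", n1), emitHap("hap2", n2))
      } else {
        spanLen <- function(n) pmin(pmax(4L, rpois(n, cfg$fragCpgSpan)), L)
        nFr <- function() {
          sl <- max(4L, min(round(cfg$fragCpgSpan), L))
          rpois(1, cfg$meanCoverage / 2 * L / sl)
        }
        mkSpans <- function(n) {
          lens <- spanLen(n)
          starts <- pmin(1L + floor(runif(n) * L),
                         pmax(1L, L - lens + 1L))
          lapply(seq_len(n), function(r)
            starts[r]:(min(L, starts[r] + lens[r] - 1L)))
        }
        n1 <- nFr(); n2 <- nFr()
        rows[[i]] <- rbind(emitHap("hap1", n1, mkSpans(n1)),
                           emitHap("hap2", n2, mkSpans(n2)))
      }
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(df))
      df <- data.frame(read_id = character(), chrom = character(),
                       pos = integer(), call = character())
    MethReads(sampleId, df)
  })
}

#' Simulate a panel of block-level count tables for caller calibration
#'
#' Builds a haplotype-resolved track over `nBlocks` blocks in which a
#' leading fraction carries planted ASM (haplotype methylation
#' difference `delta`, haplotype 1 methylated) and the rest are null
#' (both haplotypes at `baseline`); every CpG on each haplotype gets
#' exactly `adjCov` calls, so the adjusted CpG coverage equals `adjCov`.
#'
#' @param nBlocks total blocks.
#' @param asmFraction fraction with planted ASM (leading blocks).
#' @param delta planted haplotype methylation difference.
#' @param adjCov per-haplotype adjusted CpG coverage.
#' @param cpgsPerBlock CpGs per block.
#' @param baseline null methylation level (default 0.5).
#' @param errorRate per-call error.
#' @param seed RNG seed.
#' @return list: `track` ([MethTrack-class]), `blocks` (`GRanges` with
#'   `truth` metadata column in `{asm, null}`).
#' @export
simulateBlockPanel <- function(nBlocks = 2000L, asmFraction = 0,
                               delta = 0.9, adjCov = 10L,
                               cpgsPerBlock = 6L, baseline = 0.5,
                               errorRate = 0.02, seed = 1L) {
  .withSeed(seed, {
    nAsm <- round(asmFraction * nBlocks)
    pHi <- min(1 - errorRate, baseline + delta / 2)
    pLo <- max(errorRate, baseline - delta / 2)
    gapped <- cpgsPerBlock * 10L + 500L
    starts <- 1000L + (seq_len(nBlocks) - 1L) * gapped
    chrom <- "chrS"
    posList <- lapply(starts, function(s)
      s + 10L * (seq_len(cpgsPerBlock) - 1L))
    allPos <- unlist(posList)
    nPos <- length(allPos)
    isAsm <- rep(seq_len(nBlocks) <= nAsm, each = cpgsPerBlock)
    m1 <- rbinom(nPos, adjCov, ifelse(isAsm, pHi, baseline))
    m2 <- rbinom(nPos, adjCov, ifelse(isAsm, pLo, baseline))
    track <- MethTrack("panel", chrom, c(allPos, allPos),
                       meth = c(m1, m2),
                       unmeth = c(adjCov - m1, adjCov - m2),
                       haplotype = rep(c("hap1", "hap2"), each = nPos))
    blocks <- GRanges(chrom, IRanges(vapply(posList, min, 1L),
                                     vapply(posList, max, 1L)))
    mcols(blocks)$truth <- ifelse(seq_len(nBlocks) <= nAsm, "asm", "null")
    list(track = track, blocks = blocks)
  })
}

#' Simulate a multi-tissue normal panel with planted tissue-specific IMRs
#'
#' Lays out blocks on `chrS` and plants, per tissue, blocks that are
#' intermediately methylated (0.5) in that tissue but fully methylated
#' or unmethylated elsewhere (`tissue-specific`), plus pan-tissue
#' imprint-like blocks intermediate in every tissue, and background
#' blocks methylated everywhere. Per-sample "bimodal block" interval
#' sets are emitted with small boundary jitter, plus one spurious
#' private block per tissue (present in a single sample) that the
#' consistency filter must drop.
#'
#' @param nTissues,samplesPerTissue panel shape (default 3 x 3).
#' @param blocksPerTissue planted tissue-specific blocks per tissue.
#' @param nPanTissue pan-tissue intermediate (imprint-like) blocks.
#' @param nBackground constitutively methylated background blocks.
#' @param cpgsPerBlock,coverage block size and per-CpG coverage.
#' @param errorRate per-call error.
#' @param seed RNG seed.
#' @return list: `tracks` (list tissue -> list of [MethTrack-class]),
#'   `sampleBlockSets` (list tissue -> list of per-sample `GRanges`),
#'   `truth` (`GRanges` of all blocks with `label` and `tissue`).
#' @export
simulateTissuePanel <- function(nTissues = 3L, samplesPerTissue = 3L,
                                blocksPerTissue = 20L, nPanTissue = 10L,
                                nBackground = 20L, cpgsPerBlock = 10L,
                                coverage = 50L, errorRate = 0,
                                seed = 1L) {
  .withSeed(seed, {
    tissues <- paste0("tissue", seq_len(nTissues))
    labels <- c(rep(tissues, each = blocksPerTissue),
                rep("pan-tissue", nPanTissue),
                rep("background", nBackground))
    labels <- sample(labels)
    n <- length(labels)
    starts <- 10000L + (seq_len(n) - 1L) * 2000L
    posList <- lapply(starts, function(s)
      s + 15L * (seq_len(cpgsPerBlock) - 1L))
    blocks <- GRanges("chrS", IRanges(starts,
                                      vapply(posList, max, 1L)))
    mcols(blocks)$label <- labels
    mcols(blocks)$cpg_pos <- IRanges::IntegerList(posList)
    ## non-matched level alternates hyper/hypo so pan-tissue blocks are
    ## the only ones intermediate everywhere
    offLevel <- ifelse(seq_len(n) %% 2L == 0L, 0.95, 0.05)
    levelFor <- function(tissue, i) {
      switch(labels[i],
        "pan-tissue" = 0.5,
        "background" = 0.95,
        if (labels[i] == tissue) 0.5 else offLevel[i])
    }
    tracks <- lapply(tissues, function(ts)
      lapply(seq_len(samplesPerTissue), function(si) {
        p <- vapply(seq_len(n), function(i) {
          lv <- levelFor(ts, i)
          lv * (1 - errorRate) + (1 - lv) * errorRate
        }, numeric(1))
        meth <- unlist(lapply(seq_len(n), function(i)
          rbinom(cpgsPerBlock, coverage, p[i])))
        MethTrack(sprintf("%s_s%d", ts, si),
                  chrom = "chrS", pos = unlist(posList),
                  meth = meth, unmeth = coverage - meth)
      }))
    names(tracks) <- tissues
    ## per-sample bimodal block interval sets: every intermediate-in-
    ## this-tissue block, jittered, plus one private spurious block
    sampleBlockSets <- lapply(tissues, function(ts) {
      idx <- which(labels %in% c(ts, "pan-tissue"))
      lapply(seq_len(samplesPerTissue), function(si) {
        jit <- as.integer(round(runif(length(idx), -10, 10)))
        g <- GRanges("chrS", IRanges(pmax(1L, start(blocks)[idx] + jit),
                                     end(blocks)[idx] + jit))
        if (si == 1L) {
          spur <- GRanges("chrS",
                          IRanges(max(end(blocks)) + 5000L * match(ts, tissues),
                                  width = 120L))
          g <- c(g, spur)
        }
        sort(g)
      })
    })
    names(sampleBlockSets) <- tissues
    list(tracks = tracks, sampleBlockSets = sampleBlockSets,
         truth = blocks)
  })
}
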