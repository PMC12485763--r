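test_that("config validation rejects impossible parameters", {
  expect_error(simConfig(asmProb = 1.5), "probabilities")
  expect_error(simConfig(fracRandomAsm = 0.5, fracConstM = 0.1,
                         fracConstU = 0.1), "sum to 1")
  expect_error(simConfig(nClones = 0), "nClones")
})

test_that("same seed gives identical output, different seed differs", {
  cfg <- simConfig(nBlocks = 15, nCells = 100, seed = 21,
                   nImprinted = 1L, nSvAdjacent = 1L, nSnpDense = 1L,
                   nChrX = 1L)
  a <- simulatePopulation(cfg)
  b <- simulatePopulation(cfg)
  expect_identical(methCounts(a$bulk), methCounts(b$bulk))
  expect_identical(as.data.frame(a$truth$blocks),
                   as.data.frame(b$truth$blocks))
  d <- simulatePopulation(simConfig(nBlocks = 15, nCells = 100,
                                    seed = 22, nImprinted = 1L,
                                    nSvAdjacent = 1L, nSnpDense = 1L,
                                    nChrX = 1L))
  expect_false(identical(methCounts(a$bulk), methCounts(d$bulk)))

  r1 <- emitReads(a, "long", clone = NULL)
  r2 <- emitReads(b, "long", clone = NULL)
  expect_identical(readCalls(r1), readCalls(r2))
})

test_that("population bulk haplotype methylation reflects the cell mix", {
  cfg <- simConfig(nBlocks = 30, nCells = 10000L, cellCoverage = 2,
                   errorRate = 0, nImprinted = 0L, nSvAdjacent = 0L,
                   nSnpDense = 0L, nChrX = 0L, seed = 4)
  pop <- simulatePopulation(cfg)
  blocks <- pop$truth$blocks
  asm <- blocks[mcols(blocks)$label == "random-ASM"]
  for (h in c("hap1", "hap2")) {
    m <- aggregateIntervals(pop$bulk, asm, haplotype = h)$weighted_mean
    expect_true(all(abs(m - 0.5) <= 0.02))
  }
})

test_that("a single cell is clonal: full ASM in the bulk track", {
  cfg <- simConfig(nBlocks = 20, nCells = 1L, cellCoverage = 40,
                   errorRate = 0, nImprinted = 0L, nSvAdjacent = 0L,
                   nSnpDense = 0L, nChrX = 0L, seed = 8)
  pop <- simulatePopulation(cfg)
  blocks <- pop$truth$blocks
  asm <- blocks[mcols(blocks)$label == "random-ASM"]
  m1 <- aggregateIntervals(pop$bulk, asm, haplotype = "hap1")$weighted_mean
  m2 <- aggregateIntervals(pop$bulk, asm, haplotype = "hap2")$weighted_mean
  expect_true(all((m1 == 1 & m2 == 0) | (m1 == 0 & m2 == 1)))
})

test_that("bulk counts equal the per-cell column sum exactly", {
  cfg <- simConfig(nBlocks = 8, nCells = 12L, cellCoverage = 3,
                   nImprinted = 1L, nSvAdjacent = 0L, nSnpDense = 0L,
                   nChrX = 0L, seed = 13)
  pop <- simulatePopulation(cfg, perCell = TRUE)
  summed <- Reduce(`+`, lapply(pop$cellTracks, methCounts))
  expect_identical(summed, methCounts(pop$bulk))
  summedTot <- Reduce(`+`, lapply(pop$cellTracks, totalCounts))
  expect_identical(summedTot, totalCounts(pop$bulk))
})

test_that("noiseless clones have exact haplotype methylation per label", {
  cfg <- simConfig(nBlocks = 30, nClones = 3L, errorRate = 0,
                   epimutationRate = 0, nImprinted = 2L,
                   nSvAdjacent = 0L, nSnpDense = 0L, nChrX = 0L,
                   nCells = 100L, seed = 6)
  cs <- simulateCloneSet(cfg)
  blocks <- cs$truth$blocks
  lab <- mcols(blocks)$label
  for (ci in seq_along(cs$cloneTracks)) {
    tr <- cs$cloneTracks[[ci]]
    m1 <- aggregateIntervals(tr, blocks, haplotype = "hap1")$weighted_mean
    m2 <- aggregateIntervals(tr, blocks, haplotype = "hap2")$weighted_mean
    st <- cs$truth$cloneStates[, ci]
    expect_true(all(m1[st == "hap1"] == 1 & m2[st == "hap1"] == 0))
    expect_true(all(m1[st == "hap2"] == 0 & m2[st == "hap2"] == 1))
    expect_true(all(m1[lab == "constitutive-methylated"] == 1))
    expect_true(all(m2[lab == "constitutive-unmethylated"] == 0))
    expect_true(all(m1[st == "imprinted-hap1"] == 1 &
                      m2[st == "imprinted-hap1"] == 0))
  }
  ## epimutationRate = 0: no both-haplotype states planted
  expect_false(any(cs$truth$cloneStates %in% c("hyper", "hypo")))
})

test_that("clone haplotype draws follow asmProb", {
  cfg <- simConfig(nBlocks = 60, nClones = 11L, asmProb = 1.0,
                   epimutationRate = 0, nCells = 100L, nImprinted = 0L,
                   nSvAdjacent = 0L, nSnpDense = 0L, nChrX = 0L,
                   seed = 10)
  cs <- simulateCloneSet(cfg)
  st <- cs$truth$cloneStates
  lab <- mcols(cs$truth$blocks)$label
  expect_true(all(st[lab == "random-ASM", ] == "hap1"))
})

test_that("emitted long reads are pure per haplotype when noiseless", {
  cfg <- simConfig(nBlocks = 12, nClones = 2L, errorRate = 0,
                   epimutationRate = 0, nCells = 100L, nImprinted = 0L,
                   nSvAdjacent = 0L, nSnpDense = 0L, nChrX = 0L,
                   seed = 14)
  cs <- simulateCloneSet(cfg)
  reads <- emitReads(cs, "long", clone = 1L)
  df <- readCalls(reads)
  blocks <- cs$truth$blocks
  lab <- mcols(blocks)$label
  st <- cs$truth$cloneStates[, 1L]
  asmIdx <- which(lab == "random-ASM")
  for (i in asmIdx) {
    pos <- mcols(blocks)$cpg_pos[[i]]
    sub <- df[df$pos %in% pos, ]
    methHap <- if (st[i] == "hap1") "hap1" else "hap2"
    expect_true(all(sub$call[sub$hap_tag == methHap] == "M"))
    expect_true(all(sub$call[sub$hap_tag != methHap] == "U"))
  }
})

test_that("long-read depth recovers the Poisson coverage mean", {
  cfg <- simConfig(nBlocks = 100, nClones = 1L, meanCoverage = 30,
                   nCells = 100L, nImprinted = 0L, nSvAdjacent = 0L,
                   nSnpDense = 0L, nChrX = 0L, seed = 17)
  cs <- simulateCloneSet(cfg)
  reads <- emitReads(cs, "long", clone = 1L)
  depth <- table(readCalls(reads)$pos)
  expect_gte(length(depth), 1000L)
  expect_lt(abs(mean(depth) - 30), 1)
})

test_that("short fragments span >= 4 CpGs and tag SNP-overlapping reads", {
  cfg <- simConfig(nBlocks = 30, nClones = 1L, nCells = 100L,
                   nImprinted = 0L, nSvAdjacent = 0L, nSnpDense = 0L,
                   nChrX = 0L, seed = 19)
  cs <- simulateCloneSet(cfg)
  frags <- emitReads(cs, "short", clone = 1L)
  df <- readCalls(frags)
  perRead <- split(df, df$read_id)
  expect_true(all(vapply(perRead, nrow, 1L) >= 4L))
  snp <- mcols(cs$truth$blocks)$snp_pos
  tagged <- vapply(perRead, function(d) d$allele_tag[1] != "none", TRUE)
  covers <- vapply(perRead, function(d)
    any(min(d$pos) <= snp & max(d$pos) >= snp), TRUE)
  expect_identical(unname(tagged), unname(covers))
  expect_gt(sum(tagged), 0L)
})
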