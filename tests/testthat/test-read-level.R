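pos4 <- c(101, 121, 141, 161)
pos10 <- seq(101, by = 20, length.out = 10)

test_that("read classification uses the 70/30 thresholds", {
  pats <- c(paste(rep("M", 7), collapse = ""),  # 7/10 -> methylated
            paste(rep("U", 7), collapse = ""),
            paste(rep("M", 5), collapse = ""))
  mk <- function(m, u) paste(c(rep("M", m), rep("U", u)), collapse = "")
  reads <- readsFromPatterns(c(mk(7, 3), mk(3, 7), mk(5, 5)), pos10)
  cls <- classifyReads(reads, grS(90, 300))
  expect_equal(cls$class,
               c("methylated", "unmethylated", "undetermined"))
  ## a read with no in-region calls is excluded, not classified
  cls2 <- classifyReads(reads, grS(1000, 2000))
  expect_equal(nrow(cls2), 0L)
})

test_that("fragment metrics behave on canonical patterns", {
  region <- grS(90, 300)
  ## perfectly concordant fully-methylated reads
  allM <- readsFromPatterns(rep("MMMM", 10), pos4)
  m <- fragmentMetrics(allM, region)
  expect_equal(m$pdr, 0)
  expect_equal(m$entropy, 0)
  expect_equal(m$chalm, 1)
  expect_equal(m$mhl, 1)
  expect_equal(m$mcr, 1)
  expect_equal(m$mbs, 1)

  ## 50% fully-M, 50% fully-U over 4 CpGs: two patterns, 1 bit
  half <- readsFromPatterns(c(rep("MMMM", 5), rep("UUUU", 5)), pos4)
  m2 <- fragmentMetrics(half, region)
  expect_equal(m2$pdr, 0)
  expect_equal(m2$entropy, 1)
  expect_equal(m2$mean_adjacent_r2, 1)
  expect_equal(m2$chalm, 0.5)

  ## all 16 equiprobable 4-CpG patterns: 2 concordant -> pdr = 7/8
  pats16 <- apply(expand.grid(rep(list(c("M", "U")), 4)), 1,
                  paste, collapse = "")
  m3 <- fragmentMetrics(readsFromPatterns(pats16, pos4), region)
  expect_equal(m3$pdr, 7 / 8)
  expect_equal(m3$entropy, 4)          # uniform over 16 patterns
  expect_equal(m3$chalm, 15 / 16)

  ## no qualifying reads: all metrics missing
  single <- readsFromPatterns("M", pos4)
  expect_true(all(is.na(
    fragmentMetrics(single, region)[, 1:7])))
})

test_that("allele-partitioned ASM test reproduces the exact Fisher p", {
  region <- grS(90, 300)
  reads <- readsFromPatterns(
    c(rep("MMMM", 9), "UUUU",           # ref: 9 meth, 1 unmeth
      "MMMM", rep("UUUU", 9)),          # alt: 1 meth, 9 unmeth
    pos4, allele = c(rep("ref", 10), rep("alt", 10)))
  res <- testAlleleASM(reads, region)
  expect_equal(res$status, "tested")
  expect_equal(res$p, 202 / 184756, tolerance = 1e-12)
  expect_equal(c(res$ref_meth, res$ref_unmeth, res$alt_meth,
                 res$alt_unmeth), c(9L, 1L, 1L, 9L))

  ## symmetric table: p = 1, not ASM
  sym <- readsFromPatterns(
    c(rep("MMMM", 5), rep("UUUU", 5), rep("MMMM", 5), rep("UUUU", 5)),
    pos4, allele = rep(c("ref", "alt"), each = 10))
  res2 <- testAlleleASM(sym, region)
  expect_equal(res2$p, 1)
  expect_false(res2$is_asm)

  ## an allele group below 8 classified reads is skipped
  small <- readsFromPatterns(
    c(rep("MMMM", 10), rep("UUUU", 6)),
    pos4, allele = c(rep("ref", 10), rep("alt", 6)))
  expect_equal(testAlleleASM(small, region)$status, "skipped_min_reads")

  ## reads spanning < 4 in-region CpGs are dropped before counting
  short <- readsFromPatterns(
    c(rep("MMMM", 8), rep("UUUU", 8), rep("MMM", 8)),
    pos4, allele = c(rep("ref", 8), rep("alt", 8), rep("alt", 8)))
  res3 <- testAlleleASM(short, region)
  expect_equal(res3$alt_meth + res3$alt_unmeth, 8L)
})

test_that("BH adjustment matches worked examples and the naive oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(c(0.05, 1.0)), c(0.10, 1.0))
  expect_equal(bhAdjust(numeric()), numeric())
  set.seed(3)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), naiveBH(p))
  }
})

test_that("adjacent mLD r2 matches closed forms and the Pearson formula", {
  two <- c(101, 121)
  ## perfect co-methylation
  ld <- adjacentMLD(readsFromPatterns(c(rep("MM", 5), rep("UU", 5)), two))
  expect_equal(ld$r2, 1)
  ## independence
  ld2 <- adjacentMLD(readsFromPatterns(
    rep(c("MM", "MU", "UM", "UU"), each = 3), two))
  expect_equal(ld2$r2, 0)
  ## mixed table MM x4, MU x2, UU x4 -> 4/9
  ld3 <- adjacentMLD(readsFromPatterns(
    c(rep("MM", 4), rep("MU", 2), rep("UU", 4)), two))
  expect_equal(ld3$r2, 4 / 9, tolerance = 1e-12)
  ## pair coverage below 10 reads, or zero variance: undefined
  expect_true(is.na(adjacentMLD(readsFromPatterns(rep("MM", 9),
                                                  two))$r2))
  expect_true(is.na(adjacentMLD(readsFromPatterns(
    c(rep("MM", 6), rep("MU", 6)), two))$r2))  # first CpG constant

  set.seed(12)
  for (rep in 1:100) {
    n <- sample(10:30, 1)
    pats <- paste0(sample(c("M", "U"), n, TRUE),
                   sample(c("M", "U"), n, TRUE))
    ld <- adjacentMLD(readsFromPatterns(pats, two))
    x <- as.numeric(substr(pats, 1, 1) == "M")
    y <- as.numeric(substr(pats, 2, 2) == "M")
    ref <- pearsonR2(x, y)
    if (is.na(ref)) expect_true(is.na(ld$r2))
    else expect_equal(ld$r2, ref, tolerance = 1e-12)
  }
})

test_that("block discovery decomposes runs at the r2 threshold", {
  mkLD <- function(pos, r2) data.frame(
    chrom = "chrS", pos_a = pos[-length(pos)], pos_b = pos[-1],
    n_reads = 30L, r2 = r2)
  p5 <- seq(101, by = 20, length.out = 5)
  b <- findBlocks(mkLD(p5, rep(0.9, 4)))
  expect_equal(length(b), 1L)
  expect_equal(mcols(b)$n_cpgs, 5L)
  expect_equal(mcols(b)$cpg_pos[[1]], p5)

  p3 <- p5[1:3]
  expect_equal(length(findBlocks(mkLD(p3, rep(0.9, 2)))), 0L)

  p6 <- seq(101, by = 20, length.out = 6)
  b2 <- findBlocks(mkLD(p6, c(0.9, 0.9, 0.9, 0.2, 0.8)))
  expect_equal(length(b2), 1L)
  expect_equal(mcols(b2)$cpg_pos[[1]], p6[1:4])

  ## an undefined pair breaks a run exactly like a low one
  b3 <- findBlocks(mkLD(p6, c(0.9, 0.9, 0.9, NA, 0.9)))
  expect_equal(mcols(b3)$cpg_pos[[1]], p6[1:4])
})

test_that("IMR-block selection requires every normal in range", {
  pos <- seq(101, by = 20, length.out = 5)
  blocks <- grS(101, 181)
  mkNorm <- function(p, id) trackFromCounts(pos, round(p * 20),
                                            rep(20, 5), sampleId = id)
  sel <- selectIMRBlocks(blocks, list(mkNorm(0.5, "n1"), mkNorm(0.5, "n2"),
                                      mkNorm(0.5, "n3"), mkNorm(0.5, "n4")))
  expect_equal(length(sel$blocks), 1L)
  expect_equal(mcols(sel$blocks)$mean_n1, 0.5)

  sel2 <- selectIMRBlocks(blocks, list(mkNorm(0.5, "n1"),
                                       mkNorm(0.9, "n2")))
  expect_equal(length(sel2$blocks), 0L)
  expect_equal(sel2$excluded$reason, "outside_range")

  ## one sample at 0.75: consistency across all samples is required
  sel3 <- selectIMRBlocks(blocks, list(mkNorm(0.5, "n1"), mkNorm(0.5, "n2"),
                                       mkNorm(0.5, "n3"), mkNorm(0.75, "n4")))
  expect_equal(length(sel3$blocks), 0L)

  ## zero coverage in any normal excludes with a reason
  empty <- trackFromCounts(5000, 1, 2, sampleId = "n0")
  sel4 <- selectIMRBlocks(blocks, list(mkNorm(0.5, "n1"), empty))
  expect_equal(sel4$excluded$reason, "zero_coverage")
})

test_that("planted correlated blocks are recovered with exact boundaries", {
  cfg <- simConfig(nBlocks = 40, fracRandomAsm = 1, fracConstM = 0,
                   fracConstU = 0, epimutationRate = 0, nImprinted = 0L,
                   nSvAdjacent = 0L, nSnpDense = 0L, nChrX = 0L,
                   nNullBlocks = 20L, nClones = 4L, nCells = 100L,
                   seed = 23)
  cs <- simulateCloneSet(cfg)
  ## mLD from reads pooled across samples, as in multi-donor block
  ## discovery
  reads <- poolReads(lapply(1:4, function(ci)
    emitReads(cs, "long", clone = ci)))
  found <- findBlocks(adjacentMLD(reads))
  truth <- cs$truth$blocks
  planted <- truth[mcols(truth)$label == "random-ASM"]
  nulls <- truth[mcols(truth)$label == "null-independent"]
  expect_equal(length(found), length(planted))
  expect_equal(sum(countOverlaps(found, nulls)), 0L)
  ov <- findOverlaps(found, planted)
  expect_equal(length(ov), length(planted))
  for (k in seq_along(ov))
    expect_equal(mcols(found)$cpg_pos[[queryHits(ov)[k]]],
                 mcols(planted)$cpg_pos[[subjectHits(ov)[k]]])
})
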