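test_that("haplotype DMRs apply the 0.4 difference rule", {
  pos <- seq(1001, by = 50, length.out = 10)
  strong <- hapTrackExact(pos, 0.95, 0.05, depth = 20)
  d <- hapDMRs(strong)
  expect_equal(nrow(d), 1L)
  expect_equal(d$diff, 0.9, tolerance = 1e-6)

  same <- hapTrackExact(pos, 0.5, 0.5, depth = 20)
  expect_equal(nrow(hapDMRs(same)), 0L)

  ## a uniform 0.2 difference stays below the 0.4 rule at any depth
  weak <- hapTrackExact(pos, 0.6, 0.4, depth = 500)
  expect_equal(nrow(hapDMRs(weak)), 0L)

  combinedOnly <- trackFromCounts(pos, rep(5, 10), rep(10, 10))
  expect_error(hapDMRs(combinedOnly), "haplotype")
})

test_that("SNP-density masking takes strictly the top windows", {
  genome <- c(chrS = 10000000L)
  ## 990 windows with 1 SNP, 10 with 50
  set.seed(40)
  dense <- sample(0:999, 10)
  pos <- integer()
  for (w in 0:999) {
    n <- if (w %in% dense) 50L else 1L
    pos <- c(pos, w * 10000L + sample(1:9999, n))
  }
  snps <- GRanges("chrS", IRanges(sort(pos), width = 1))
  masked <- highSnpDensityWindows(snps, genome)
  expect_equal(length(masked), 10L)
  expect_setequal(start(masked), dense * 10000L + 1L)

  ## flat density masks nothing; so does an empty SNP set
  flat <- GRanges("chrS", IRanges(seq(1, 1e7, by = 10000), width = 1))
  expect_equal(length(highSnpDensityWindows(flat, genome)), 0L)
  expect_equal(length(highSnpDensityWindows(GRanges(), genome)), 0L)
})

test_that("the ASM region filter excludes by reason with precedence", {
  regions <- GRanges(c("chrX", "chrS", "chrS", "chrS", "chrS"),
                     IRanges(c(1000, 5000, 20000, 41000, 100000),
                             width = 200))
  imprinted <- grS(4900, 5300)
  sv <- grS(21000, 21000)          # 800 bp from region 3's end
  dense <- grS(40001, 50000)
  res <- asmRegionFilter(regions, imprinted = imprinted,
                         svBreakpoints = sv, snpDenseWindows = dense)
  expect_equal(res$excluded$reason,
               c("sex_chrom", "imprinted", "sv_proximity", "snp_dense"))
  expect_equal(start(res$retained), 100000L)

  ## a breakpoint farther than 1000 bp does not exclude
  far <- asmRegionFilter(grS(20000, 20200),
                         svBreakpoints = grS(21500, 21500))
  expect_equal(length(far$retained), 1L)
  near <- asmRegionFilter(grS(20000, 20200),
                          svBreakpoints = grS(21100, 21100))
  expect_equal(length(near$retained), 0L)
})

test_that("block ASM test enforces coverage rules and effect size", {
  pos <- seq(1001, by = 20, length.out = 10)
  block <- grS(1001, 1181)
  ## hap1 fully methylated (6 calls/CpG), hap2 fully unmethylated
  tr <- MethTrack("s", "chrS", c(pos, pos),
                  meth = c(rep(6, 10), rep(0, 10)),
                  unmeth = c(rep(0, 10), rep(6, 10)),
                  haplotype = rep(c("hap1", "hap2"), each = 10))
  res <- blockASMTest(block, tr)
  expect_equal(res$adj_cov_hap1, 6)
  expect_equal(res$diff, 1)
  expect_true(res$is_asm)
  expect_equal(res$methylated_hap, "hap1")

  ## adjusted coverage 4 on hap2: not evaluable
  tr2 <- MethTrack("s", "chrS", c(pos, pos),
                   meth = c(rep(6, 10), rep(0, 10)),
                   unmeth = c(rep(0, 10), rep(4, 10)),
                   haplotype = rep(c("hap1", "hap2"), each = 10))
  res2 <- blockASMTest(block, tr2)
  expect_equal(res2$status, "not_evaluable")
  expect_false(res2$is_asm)

  ## significant but |diff| = 0.35: not ASM
  tr3 <- hapTrackExact(pos, 0.675, 0.325, depth = 400)
  res3 <- blockASMTest(block, tr3)
  expect_lt(res3$q, 1e-10)
  expect_equal(res3$diff, 0.35, tolerance = 1e-9)
  expect_false(res3$is_asm)
})

test_that("block epimutation test direction and thresholds", {
  pos <- seq(1001, by = 20, length.out = 10)
  block <- grS(1001, 1181)
  mkC <- function(m, u, id) trackFromCounts(pos, rep(m, 10),
                                            rep(m + u, 10), sampleId = id)
  ## sample 95% vs normal 50%: hyper, diff 0.45
  res <- blockEpimutationTest(block, mkC(19, 1, "s"), mkC(10, 10, "n"))
  expect_true(res$is_epimutation)
  expect_equal(res$direction, "hyper")
  expect_equal(res$diff, 0.45, tolerance = 1e-9)

  resNull <- blockEpimutationTest(block, mkC(10, 10, "s"),
                                  mkC(10, 10, "n"))
  expect_false(resNull$is_epimutation)
  expect_equal(resNull$direction, "none")

  ## |diff| = 0.25 fails the > 0.3 rule even when highly significant
  res25 <- blockEpimutationTest(block, mkC(300, 100, "s"),
                                mkC(200, 200, "n"))
  expect_lt(res25$q, 1e-10)
  expect_false(res25$is_epimutation)

  ## hypomethylation direction
  resHypo <- blockEpimutationTest(block, mkC(1, 19, "s"),
                                  mkC(10, 10, "n"))
  expect_equal(resHypo$direction, "hypo")
})

test_that("block states classify with ASM precedence", {
  asm <- data.frame(is_asm = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                    methylated_hap = c("hap2", "none", "none", "none",
                                       "hap1"))
  epi <- data.frame(is_epimutation = c(FALSE, TRUE, FALSE, FALSE, TRUE),
                    direction = c("none", "hyper", "none", "none",
                                  "hypo"),
                    sample_mean = c(0.5, 0.95, 0.5, 0.95, 0.1))
  st <- classifyBlockState(asm, epi)
  expect_equal(st, c("ASM_hap2_meth", "hyper", "intermediate",
                     "indeterminate", "ASM_hap1_meth"))
})

test_that("planted confounders are excluded exactly, clean blocks kept", {
  cfg <- simConfig(nBlocks = 60, nCells = 500L, seed = 29)
  pop <- simulatePopulation(cfg)
  truth <- pop$truth$blocks
  masks <- pop$truth$masks
  dense <- highSnpDensityWindows(masks$snps, masks$genome,
                                 window = cfg$snpWindow,
                                 topFraction = cfg$snpTopFraction)
  res <- asmRegionFilter(granges(truth), imprinted = masks$imprinted,
                         svBreakpoints = masks$svBreakpoints,
                         snpDenseWindows = dense)
  lab <- mcols(truth)$label
  confounder <- lab %in% c("chrX", "imprinted", "SV-adjacent",
                           "SNP-dense")
  expect_equal(nrow(res$excluded), sum(confounder))
  expect_equal(length(res$retained), sum(!confounder))
  expected <- c(chrX = "sex_chrom", imprinted = "imprinted",
                `SV-adjacent` = "sv_proximity",
                `SNP-dense` = "snp_dense")
  key <- paste(res$excluded$chrom, res$excluded$start)
  truthKey <- paste(as.character(seqnames(truth)), start(truth))
  expect_setequal(key, truthKey[confounder])
  expect_equal(res$excluded$reason,
               unname(expected[lab[match(key, truthKey)]]))
})
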