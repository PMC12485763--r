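test_that("bedmethyl parsing converts coordinates and collapses strands", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t101\t5\t10",
               "chr1\t200\t201\t0\t0"), f)
  tr <- readBedmethyl(f, "s1")
  expect_equal(start(cpgRanges(tr)), c(101L, 201L))  # 1-based internal
  expect_equal(methCounts(tr), c(5L, 0L))
  expect_equal(unmethCounts(tr), c(5L, 0L))
  expect_equal(methFraction(tr), c(0.5, NA_real_))   # 0-depth retained

  ## adjacent forward/reverse records of one CpG collapse by count sum
  f2 <- withr::local_tempfile()
  writeLines(c("chr1\t100\t101\t3\t5",
               "chr1\t101\t102\t2\t5"), f2)
  tr2 <- readBedmethyl(f2)
  expect_equal(length(tr2), 1L)
  expect_equal(start(cpgRanges(tr2)), 101L)
  expect_equal(methCounts(tr2), 5L)
  expect_equal(totalCounts(tr2), 10L)

  ## explicit strand column: "-" records shift back one base
  f3 <- withr::local_tempfile()
  writeLines(c("chr1\t100\t101\t3\t5\t+",
               "chr1\t101\t102\t2\t5\t-",
               "chr1\t104\t105\t1\t4\t+"), f3)
  tr3 <- readBedmethyl(f3)
  expect_equal(start(cpgRanges(tr3)), c(101L, 105L))
  expect_equal(totalCounts(tr3), c(10L, 4L))
})

test_that("bedmethyl parser rejects malformed and negative input", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\t101\t-2\t5", f)
  expect_error(readBedmethyl(f), "negative")
  f2 <- withr::local_tempfile()
  writeLines("chr1\t100\t101\t9\t5", f2)
  expect_error(readBedmethyl(f2), "exceeds")
  f3 <- withr::local_tempfile()
  writeLines("chr1\t100", f3)
  expect_error(readBedmethyl(f3))
})

test_that("track write-then-parse round-trips counts exactly", {
  set.seed(11)
  pos <- sort(sample(1000:200000, 300))
  pos <- pos[diff(c(0, pos)) > 1]            # avoid adjacency collapse
  tot <- rpois(length(pos), 20)
  tr <- trackFromCounts(pos, rbinom(length(pos), tot, 0.4), tot)
  f <- withr::local_tempfile()
  writeBedmethyl(tr, f)
  tr2 <- readBedmethyl(f)
  expect_equal(start(cpgRanges(tr2)), start(cpgRanges(tr)))
  expect_equal(methCounts(tr2), methCounts(tr))
  expect_equal(unmethCounts(tr2), unmethCounts(tr))
})

test_that("read tables parse, propagate tags, and round-trip", {
  f <- withr::local_tempfile()
  writeLines(c("read_id\tchrom\tpos\tcall\tallele_tag\thap_tag",
               "r1\tchr1\t30\tM\tnone\thap2",
               "r1\tchr1\t10\tM\tnone\thap2",
               "r1\tchr1\t20\tU\tnone\thap2"), f)
  rd <- readReadTable(f)
  df <- readCalls(rd)
  expect_equal(df$pos, c(11L, 21L, 31L))     # sorted, 1-based
  expect_equal(df$call, c("M", "U", "M"))
  expect_equal(unique(df$hap_tag), "hap2")

  empty <- withr::local_tempfile(); file.create(empty)
  expect_equal(length(readReadTable(empty)), 0L)

  f2 <- withr::local_tempfile()
  writeLines(c("read_id\tchrom\tpos\tcall",
               "r1\tchr1\t10\tM", "r1\tchr1\t10\tU"), f2)
  expect_error(readReadTable(f2), "duplicate")
  f3 <- withr::local_tempfile()
  writeLines(c("read_id\tchrom\tpos\tcall", "r1\tchr1\t10\tX"), f3)
  expect_error(readReadTable(f3), "call symbol")

  out <- withr::local_tempfile()
  writeReadTable(rd, out)
  rd2 <- readReadTable(out)
  expect_equal(readCalls(rd2), readCalls(rd))
})

test_that("mergeIntervals applies gap and minimum-size rules", {
  ## overlap union at max_gap = 0 (on-disk [0,100) + [50,150))
  m <- mergeIntervals(grS(c(1, 51), c(100, 150)))
  expect_equal(as.data.frame(m)[, 2:3], data.frame(start = 1, end = 150))
  ## gap of 40 < 50 merges
  m2 <- mergeIntervals(grS(c(1, 141), c(100, 200)), maxGap = 50)
  expect_equal(length(m2), 1L)
  expect_equal(c(start(m2), end(m2)), c(1L, 200L))
  ## gap of exactly 50 does not merge
  m3 <- mergeIntervals(grS(c(1, 151), c(100, 250)), maxGap = 50)
  expect_equal(length(m3), 2L)
  ## short intervals dropped
  expect_equal(length(mergeIntervals(grS(1, 30), minSize = 50)), 0L)
  expect_equal(length(mergeIntervals(GRanges())), 0L)
})

test_that("mergeIntervals is idempotent on random inputs", {
  set.seed(42)
  for (rep in 1:20) {
    s <- sample(1:5000, 30)
    gr <- grS(s, s + sample(10:400, 30, replace = TRUE))
    m1 <- mergeIntervals(gr, maxGap = 50, minSize = 50)
    m2 <- mergeIntervals(m1, maxGap = 50, minSize = 50)
    expect_identical(as.data.frame(m1), as.data.frame(m2))
  }
})

test_that("multiIntersect counts sets per segment", {
  sets30 <- replicate(30, grS(1001, 1200), simplify = FALSE)
  seg <- multiIntersect(sets30)
  expect_equal(length(seg), 1L)
  expect_equal(mcols(seg)$count, 30L)

  seg2 <- multiIntersect(list(grS(1, 100), grS(51, 150)))
  expect_equal(start(seg2), c(1L, 51L, 101L))
  expect_equal(end(seg2), c(50L, 100L, 150L))
  expect_equal(mcols(seg2)$count, c(1L, 2L, 1L))

  ## an empty input set leaves counts unchanged
  seg3 <- multiIntersect(list(grS(1, 100), grS(51, 150), GRanges()))
  expect_equal(as.data.frame(seg3), as.data.frame(seg2))
})

test_that("multiIntersect matches per-base brute-force coverage", {
  set.seed(7)
  for (rep in 1:10) {
    nSets <- sample(2:10, 1)
    sets <- lapply(seq_len(nSets), function(i) {
      s <- sample(1:900, sample(1:5, 1))
      grS(s, pmin(1000, s + sample(5:200, length(s), replace = TRUE)))
    })
    seg <- multiIntersect(sets)
    ## check every base of every segment, plus segment homogeneity
    for (k in seq_along(seg)) {
      bases <- start(seg)[k]:end(seg)[k]
      cnt <- bruteCoverageCounts(sets, bases)
      expect_true(all(cnt == mcols(seg)$count[k]))
    }
    ## bases outside segments are covered by no set
    outside <- setdiff(1:1000, unlist(lapply(seq_along(seg), function(k)
      start(seg)[k]:end(seg)[k])))
    if (length(outside))
      expect_true(all(bruteCoverageCounts(sets, outside) == 0L))
  }
})

test_that("modkit-style dialect is accepted through column mapping", {
  f <- withr::local_tempfile()
  writeLines(c(paste("chr1", 100, 101, "m", 10, "+", 100, 101,
                     "255,0,0", 10, 80, 8, 2, 0, 0, 0, 0, 0,
                     sep = "\t"),
               paste("chr1", 101, 102, "m", 6, "-", 101, 102,
                     "255,0,0", 6, 50, 3, 3, 0, 0, 0, 0, 0,
                     sep = "\t")), f)
  tr <- readBedmethyl(f, dialect = "modkit")
  expect_equal(length(tr), 1L)                 # strand-collapsed
  expect_equal(start(cpgRanges(tr)), 101L)
  expect_equal(methCounts(tr), 11L)
  expect_equal(totalCounts(tr), 16L)
})
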