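writeSam <- function(lines) {
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  f
}

test_that("a single spanning read gives coverage 1.0 and MAPQ filtering zeroes it", {
  tg <- parseTarget("1:1001-1100")
  fx <- simulateSamFixture(tg, 1)
  sam <- writeSam(fx$sam)
  expect_equal(unname(as.numeric(targetCoverage(sam, tg))), 1.0)
  ## same read at MAPQ 0 under the default threshold of 20
  lines <- fx$sam
  lines[length(lines)] <- sub("\t60\t", "\t0\t", lines[length(lines)])
  expect_equal(unname(as.numeric(targetCoverage(writeSam(lines), tg))), 0.0)
})

test_that("overlapping mates count once per fragment, twice per read", {
  ## mates [1001-1100] and [1051-1150] over target 1001-1150
  tg <- parseTarget("1:1001-1150")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:1\tLN:10000",
           "@RG\tID:rg1\tSM:P1")
  pair <- c(
    paste("frag1", 99, 1, 1001, 60, "100M", "=", 1051, 150,
          strrep("A", 100), "*", sep = "\t"),
    paste("frag1", 147, 1, 1051, 60, "100M", "=", 1001, -150,
          strrep("A", 100), "*", sep = "\t"))
  sam <- writeSam(c(hdr, pair))
  expect_equal(unname(as.numeric(targetCoverage(sam, tg))), 1.0)
  covRead <- targetCoverage(sam, tg, coverageFilters(countUnit = "read"))
  expect_equal(unname(as.numeric(covRead)), 4 / 3)
  ## both match the brute-force per-base tally
  expect_equal(unname(as.numeric(targetCoverage(sam, tg))),
               bruteCoverage(c(hdr, pair), tg, unit = "fragment"))
  expect_equal(unname(as.numeric(covRead)),
               bruteCoverage(c(hdr, pair), tg, unit = "read"))
})

test_that("CIGAR deletions consume reference but are not counted as depth", {
  tg <- parseTarget("1:1001-1100")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:1\tLN:10000")
  rd <- paste("r1", 0, 1, 1001, 60, "40M20D40M", "*", 0, 0,
              strrep("A", 80), "*", sep = "\t")
  sam <- writeSam(c(hdr, rd))
  expect_equal(unname(as.numeric(targetCoverage(sam, tg))), 0.8)
  expect_equal(unname(as.numeric(targetCoverage(sam, tg))),
               bruteCoverage(c(hdr, rd), tg))
})

test_that("crafted fixtures match the brute-force tally exactly", {
  tg <- parseTarget(c("1:1001-1100", "1:2001-2150", "2:501-700"))
  fx <- simulateSamFixture(tg, c(3, 2, 1),
                           extras = c("mapq0", "duplicate",
                                      "overlapping_mates"))
  sam <- writeSam(fx$sam)
  covF <- unname(as.numeric(targetCoverage(sam, tg)))
  covR <- unname(as.numeric(
    targetCoverage(sam, tg, coverageFilters(countUnit = "read"))))
  expect_equal(covF, fx$expectedFragment)
  expect_equal(covR, fx$expectedRead)
  expect_equal(covF, bruteCoverage(fx$sam, tg, unit = "fragment"))
  expect_equal(covR, bruteCoverage(fx$sam, tg, unit = "read"))
  ## duplicates included on demand
  withDup <- targetCoverage(sam, tg, coverageFilters(includeDuplicates = TRUE))
  expect_equal(unname(as.numeric(withDup))[1], fx$expectedFragment[1] + 1)
})

test_that("splitting a target into adjacent halves preserves the length-weighted mean", {
  tg <- parseTarget("1:1001-1200")
  halves <- parseTarget(c("1:1001-1100", "1:1101-1200"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:1\tLN:10000")
  set.seed(5)
  reads <- vapply(1:20, function(i) {
    pos <- sample(900:1180, 1)
    paste(sprintf("r%d", i), 0, 1, pos, 60, "80M", "*", 0, 0,
          strrep("A", 80), "*", sep = "\t")
  }, "")
  reads <- reads[order(as.integer(vapply(strsplit(reads, "\t"), `[`, "", 4)))]
  sam <- writeSam(c(hdr, reads))
  whole <- unname(as.numeric(targetCoverage(sam, tg)))
  half <- unname(as.numeric(targetCoverage(sam, halves)))
  expect_equal(whole, sum(half * 100) / 200)
})

test_that("cohort matrix rows follow input order and empty files give zero rows", {
  tg <- parseTarget(c("1:1001-1100", "1:2001-2100"))
  fx1 <- simulateSamFixture(tg, c(2, 1), sample = "A")
  fx2 <- simulateSamFixture(tg, c(0, 3), sample = "B")
  s1 <- writeSam(fx1$sam); s2 <- writeSam(fx2$sam)
  m12 <- coverageMatrix(c(s1, s2), tg)
  expect_equal(sampleIds(m12), c("A", "B"))
  expect_equal(unname(depths(m12)), rbind(c(2, 1), c(0, 3)))
  m21 <- coverageMatrix(c(s2, s1), tg)
  expect_equal(unname(depths(m21)), unname(depths(m12))[2:1, ])
  ## header-only file: all-zero row
  empty <- writeSam(fx1$sam[startsWith(fx1$sam, "@")])
  m0 <- coverageMatrix(empty, tg)
  expect_equal(unname(depths(m0)), matrix(0, 1, 2))
  ## target chromosome missing from the header warns and yields 0
  tg3 <- parseTarget(c("1:1001-1100", "9:1-100"))
  expect_warning(cov3 <- targetCoverage(s1, tg3), "absent")
  expect_equal(unname(as.numeric(cov3))[2], 0)
})
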