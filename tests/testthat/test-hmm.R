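params <- hmmParameters()
p <- 1e-8; q <- 1 / 6; D <- 7e4; M <- 3

test_that("transition matrices interpolate between T0 and the stationary rows", {
  ## chromosome break: every row is the CNV-start distribution
  Tinf <- transitionMatrix(Inf, params)
  for (i in 1:3) expect_equal(unname(Tinf[i, ]), c(p, 1 - 2 * p, p))
  ## zero distance: pure T0
  T0 <- transitionMatrix(0, params)
  expect_equal(unname(T0["DEL", ]), c(1 - q, q, 0))
  expect_equal(unname(T0["DUP", ]), c(0, q, 1 - q))
  ## d = D mixes with weight e^-1
  TD <- transitionMatrix(D, params)
  f <- exp(-1)
  expect_equal(TD["DEL", "DEL"], f * (1 - q) + (1 - f) * p)
  expect_equal(TD["DIP", "DUP"], f * p + (1 - f) * p)
  ## rows sum to one across the distance range
  for (d in c(0, 1, 1e3, 7e4, 1e7, Inf))
    expect_lt(max(abs(rowSums(transitionMatrix(d, params)) - 1)), 1e-12)
  expect_error(transitionMatrix(-1), "non-negative")
})

test_that("emission log-densities are shifted unit normals", {
  expect_equal(emissionLogDensity(0, "DIP"), -0.5 * log(2 * pi))
  expect_equal(emissionLogDensity(M, "DUP"), emissionLogDensity(0, "DIP"))
  expect_equal(emissionLogDensity(-M, "DEL"), emissionLogDensity(0, "DIP"))
  ## at z = -M the DEL and DUP densities differ by exactly 2 M^2 nats
  expect_equal(emissionLogDensity(-M, "DEL") - emissionLogDensity(-M, "DUP"),
               2 * M^2)
})

test_that("Viterbi decodes planted events and matches exhaustive search", {
  tg <- randomTargets(4)
  expect_equal(viterbiPath(rep(0, 4), tg, params)$states, rep("DIP", 4))
  tgA <- parseTarget(sprintf("1:%d-%d", c(1, 201, 401, 601),
                             c(100, 300, 500, 700)))
  ## two adjacent z = -5 targets outweigh the 1e-8 entry cost; the same
  ## chain with z = -4 stays diploid (enumeration agrees in the loop below)
  z <- c(0, -5, -5, 0)
  expect_equal(viterbiPath(z, tgA, params)$states,
               c("DIP", "DEL", "DEL", "DIP"))
  expect_equal(viterbiPath(c(0, -4, -4, 0), tgA, params)$states,
               rep("DIP", 4))
  expect_equal(viterbiPath(z, tgA, params)$stateIdx, oracleHMM(z, tgA)$path)
  set.seed(77)
  for (i in 1:60) {
    T_ <- sample(2:8, 1)
    tg <- randomTargets(T_)
    z <- runif(T_, -8, 8)
    o <- oracleHMM(z, tg)
    v <- viterbiPath(z, tg, params)
    expect_equal(v$stateIdx, o$path)
  }
})

test_that("scaled forward/backward matches enumeration and closes at T = 1", {
  tg1 <- parseTarget("1:1-100")
  z1 <- 1.3
  fb1 <- forwardBackward(z1, tg1, params)
  expect_equal(fb1$loglik,
               log(p * dnorm(z1, -M) + (1 - 2 * p) * dnorm(z1, 0) +
                     p * dnorm(z1, M)))
  set.seed(101)
  for (i in 1:60) {
    T_ <- sample(2:8, 1)
    tg <- randomTargets(T_)
    z <- runif(T_, -8, 8)
    fb <- forwardBackward(z, tg, params)
    expect_equal(fb$loglik, oracleHMM(z, tg)$loglik, tolerance = 1e-9)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-12)
  }
})

test_that("scaled, log-sum-exp and naive likelihoods agree where all are finite", {
  set.seed(55)
  tg <- randomTargets(12)
  z <- runif(12, -4, 4)
  ll <- hmmLogLikelihood(z, tg, params, "scaled")
  expect_equal(hmmLogLikelihood(z, tg, params, "logsumexp"), ll,
               tolerance = 1e-9)
  expect_equal(hmmLogLikelihood(z, tg, params, "naive"), ll,
               tolerance = 1e-9)
})

test_that("long informative chains underflow the naive forward but not the scaled one", {
  set.seed(66)
  T_ <- 200
  tg <- parseTarget(sprintf("1:%d-%d", seq(1, by = 400, length.out = T_),
                            seq(200, by = 400, length.out = T_)))
  z <- rep(c(-6, 6, -5.5, 5.5), length.out = T_)
  expect_identical(hmmLogLikelihood(z, tg, params, "naive"), -Inf)
  llScaled <- hmmLogLikelihood(z, tg, params, "scaled")
  expect_true(is.finite(llScaled))
  expect_equal(hmmLogLikelihood(z, tg, params, "logsumexp"), llScaled,
               tolerance = 1e-9)
  fb <- forwardBackward(z, tg, params)
  expect_false(any(!is.finite(fb$gamma)))
})

test_that("state runs segment into calls and stop at chromosome breaks", {
  tg <- randomTargets(4)
  seg <- segmentPath(c(2L, 1L, 1L, 2L), tg)
  expect_equal(seg, data.frame(type = "DEL", first = 2L, last = 3L))
  expect_equal(nrow(segmentPath(rep(2L, 4), tg)), 0L)
  tgBreak <- parseTarget(c("1:1-100", "1:201-300", "2:1-100", "2:201-300"))
  seg2 <- segmentPath(c(1L, 1L, 1L, 1L), tgBreak)
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$first, c(1L, 3L))
  expect_equal(seg2$last, c(2L, 4L))
})

test_that("phred conversion rounds half up and clamps to [0, 99]", {
  expect_identical(phredQuality(0.9), 10L)
  expect_identical(phredQuality(1 - 1e-12), 99L)
  expect_identical(phredQuality(1), 99L)
  expect_identical(phredQuality(0), 0L)
  expect_identical(phredQuality(0.99), 20L)
  expect_identical(phredQuality(c(0.5, 0.999)), c(3L, 30L))
})

test_that("the five call qualities equal brute-force path sums", {
  ## degenerate single-target call: P_SOME = P_EXACT = posterior
  tg1 <- parseTarget("1:1-100")
  fb1 <- forwardBackward(-8, tg1, params)
  qs <- callQualities(1, 1, "DEL", fb1)
  expect_equal(qs$probabilities[["P_SOME"]], unname(fb1$gamma[1, "DEL"]),
               tolerance = 1e-12)
  expect_equal(qs$probabilities[["P_EXACT"]], unname(fb1$gamma[1, "DEL"]),
               tolerance = 1e-12)
  set.seed(202)
  for (i in 1:40) {
    T_ <- sample(2:6, 1)
    tg <- randomTargets(T_)
    z <- runif(T_, -8, 8)
    a <- sample(T_, 1); b <- a + sample.int(T_ - a + 1L, 1) - 1L
    type <- sample(c("DEL", "DUP"), 1)
    fb <- forwardBackward(z, tg, params)
    got <- callQualities(a, b, type, fb)$probabilities
    want <- oracleHMM(z, tg)$callProbs(a, b, match(type, c("DEL", "DIP", "DUP")))
    expect_lt(max(abs(got - want)), 1e-9)
    ## event inclusion: exact within some within non-diploid
    expect_lte(got[["P_EXACT"]], got[["P_SOME"]] + 1e-12)
    expect_lte(got[["P_SOME"]], got[["P_NON_DIPLOID"]] + 1e-12)
  }
  expect_error(callQualities(0, 2, "DEL", fb1), "outside")
})

test_that("edge-target calls pin the dropped-flank boundary convention", {
  ## a deletion starting at the first target of the chain: the nonexistent
  ## left flank imposes no constraint
  set.seed(303)
  tg <- randomTargets(5)
  z <- c(-5, -5, 0.5, 0.2, 0.1)
  fb <- forwardBackward(z, tg, params)
  got <- callQualities(1, 2, "DEL", fb)$probabilities
  want <- oracleHMM(z, tg)$callProbs(1, 2, 1)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("discovery finds planted CNVs, suppresses weak ones, and ignores sample order", {
  mkz <- function(zmat) {
    T_ <- ncol(zmat)
    tg <- parseTarget(sprintf("1:%d-%d", seq(1, by = 300, length.out = T_),
                              seq(150, by = 300, length.out = T_)))
    rdm <- ReadDepthMatrix(abs(zmat), tg)
    rdm@depths <- zmat
    rdm@stage <- "zscored"
    rdm
  }
  ## all-diploid cohort: no calls
  z0 <- matrix(0, 2, 10, dimnames = list(c("A", "B"), NULL))
  expect_equal(nrow(discoverCNVs(mkz(z0), params = params)), 0L)
  ## a 5-target z ~ -3.5 stretch yields exactly one confident DEL call
  z1 <- matrix(rnorm(3 * 30, 0, 0.3), 3, 30,
               dimnames = list(c("A", "B", "C"), NULL))
  z1[2, 11:15] <- -3.5
  calls <- discoverCNVs(mkz(z1), params = params)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$SAMPLE, "B")
  expect_equal(calls$CNV, "DEL")
  expect_equal(calls$TARGETS, "11..15")
  expect_gte(calls$Q_SOME, 30)
  expect_equal(calls$MEAN_RD, mean(z1[2, 11:15]))
  ## permuting samples yields the identical call set
  z1p <- z1[c(3, 1, 2), ]
  callsP <- discoverCNVs(mkz(z1p), params = params)
  expect_equal(callsP[order(callsP$SAMPLE), ], calls[order(calls$SAMPLE), ],
               ignore_attr = TRUE)
  ## a single-target z = -9 spike is decoded DEL but its Q_SOME (the
  ## brute-force posterior, ~0.9, phred ~10) sits below 30 and is suppressed
  z2 <- matrix(0, 1, 12, dimnames = list("A", NULL))
  z2[1, 6] <- -9
  tg2 <- targets(mkz(z2))
  expect_equal(viterbiPath(z2[1, ], tg2, params)$states[6], "DEL")
  pSome <- oracleHMM(z2[1, ], tg2)$callProbs(6, 6, 1)[["P_SOME"]]
  expect_lt(phredQuality(pSome), 30)
  expect_equal(nrow(discoverCNVs(mkz(z2), params = params)), 0L)
  relaxed <- hmmParameters(minSomeQuality = 0L)
  expect_equal(nrow(discoverCNVs(mkz(z2), params = relaxed)), 1L)
})

test_that(".xcnv files round-trip and concordance matching is overlap-aware", {
  z1 <- matrix(rnorm(3 * 30, 0, 0.3), 3, 30,
               dimnames = list(c("A", "B", "C"), NULL))
  z1[2, 11:15] <- -3.5
  z1[3, 20:24] <- 3.6
  tg <- parseTarget(sprintf("1:%d-%d", seq(1, by = 300, length.out = 30),
                            seq(150, by = 300, length.out = 30)))
  rdm <- ReadDepthMatrix(abs(z1), tg); rdm@depths <- z1
  rdm@stage <- "zscored"
  orig <- ReadDepthMatrix(matrix(100, 3, 30,
                                 dimnames = list(rownames(z1), NULL)), tg)
  calls <- discoverCNVs(rdm, orig, params)
  expect_equal(sort(calls$CNV), c("DEL", "DUP"))
  expect_equal(calls$MEAN_ORIG_RD, c(100, 100))
  f <- tempfile(fileext = ".xcnv")
  writeXcnv(calls, f)
  back <- readXcnv(f)
  expect_equal(back$INTERVAL, calls$INTERVAL)
  expect_equal(back$Q_SOME, calls$Q_SOME)
  expect_equal(back$NUM_TARG, calls$NUM_TARG)
  ## identical sets: all exact
  rep1 <- matchCalls(back, back)
  expect_equal(rep1$exact, 2L)
  expect_equal(rep1$overlap + rep1$unmatched, 0L)
  ## shift one call by one target: overlap match with difference 1
  shifted <- back
  shifted$START[1] <- GenomicRanges::start(tg)[12]
  shifted$NUM_TARG[1] <- 4L
  rep2 <- matchCalls(back, shifted)
  expect_equal(rep2$exact, 1L)
  expect_equal(rep2$overlap, 1L)
  expect_equal(rep2$pairs$targetDiff[rep2$pairs$match == "overlap"], 1L)
  ## empty call list: header-only file
  writeXcnv(calls[0, ], f)
  expect_length(readLines(f), 1L)
  expect_equal(nrow(readXcnv(f)), 0L)
})
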