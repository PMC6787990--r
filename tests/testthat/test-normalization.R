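test_that("pre-filters exclude targets by length, depth, GC and complexity", {
  sim <- smallCohort(seed = 2, nSamples = 6, nTargets = 20, batchRank = 0)
  rdm <- sim$matrix
  tg <- targets(rdm)
  GenomicRanges::mcols(tg)$gc[3] <- 0.95          # > maxGC 0.9
  GenomicRanges::mcols(tg)$complexity[5] <- 0.4   # > maxComplexity 0.25
  GenomicRanges::end(tg)[7] <- GenomicRanges::start(tg)[7] + 4  # length 5
  rdm@targets <- tg
  d <- depths(rdm); d[, 9] <- 2; rdm@depths <- d  # mean depth < 10
  res <- filterTargets(rdm)
  expect_equal(nrow(res$report), 4L)
  expect_setequal(res$report$reasons,
                  c("gc", "complexity", "length", "mean_rd"))
  expect_equal(ncol(depths(res$matrix)), 16L)
})

test_that("sample filters remove out-of-range mean and SD", {
  sim <- smallCohort(seed = 4, nSamples = 10, nTargets = 30, batchRank = 0)
  rdm <- sim$matrix
  d <- depths(rdm)
  d[2, ] <- 10                                    # mean 10 < min 25
  d[5, ] <- d[5, ] + rep(c(0, 400), length.out = ncol(d))  # SD > 150
  rdm@depths <- d
  res <- filterSamples(rdm)
  expect_equal(res$report$sample, sampleIds(sim$matrix)[c(2, 5)])
  expect_equal(nrow(depths(res$matrix)), 8L)
})

test_that("centering zeroes every target column mean", {
  m <- ReadDepthMatrix(
    matrix(c(1, 3, 5, 5, 2, 8), 2, byrow = TRUE,
           dimnames = list(c("a", "b"), NULL)),
    parseTarget(c("1:1-10", "1:20-30", "1:40-50")))
  cen <- centerTargets(m)
  expect_equal(unname(depths(cen)),
               rbind(c(-2, 0.5, -1.5), c(2, -0.5, 1.5)))
  sim <- smallCohort(seed = 6, nSamples = 15, nTargets = 40)
  cen2 <- centerTargets(sim$matrix)
  expect_lt(max(abs(colMeans(depths(cen2)))), 1e-12)
  expect_identical(stageLabel(cen2), "filtered_centered")
  one <- ReadDepthMatrix(matrix(1, 1, 1, dimnames = list("a", NULL)),
                         parseTarget("1:1-10"))
  expect_error(centerTargets(one), "at least 2 samples")
})

test_that("truncated SVD recovers known singular values", {
  set.seed(9)
  U <- qr.Q(qr(matrix(rnorm(36), 6)))
  V <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:6]
  X <- U %*% diag(c(3, 2, 1, 0, 0, 0)) %*% t(V)
  sp <- truncatedSVD(X, 3)
  expect_equal(sp@variances, c(9, 4, 1), tolerance = 1e-10)
  expect_equal(sp@n, 6L)
  ## rank-1 matrix: second variance collapses
  r1 <- outer(rnorm(5), rnorm(7))
  sp1 <- truncatedSVD(r1, 2)
  expect_gt(sp1@variances[1], 0)
  expect_lt(sp1@variances[2] / sp1@variances[1], 1e-20)
  ## truncated variances match the full decomposition
  Y <- matrix(rnorm(20 * 50), 20)
  expect_equal(truncatedSVD(Y, 5)@variances, svd(Y)$d[1:5]^2,
               tolerance = 1e-8)
  expect_error(truncatedSVD(Y, 0), "k must be")
  expect_error(truncatedSVD(Y, 21), "k must be")
})

test_that("the iterative rank selection reproduces its worked example", {
  ## spectrum (100, 50, 10, 1 x 7), n = 10: at k = 4 the over-bound is
  ## 161 + 5*1 = 166 (cutoff 11.62 -> K = 2) and the under-bound 161
  ## (cutoff 11.27) retires v_3 = 10, certifying K = 2 -- the same K as
  ## the full-spectrum cutoff 0.7 * 167 / 10 = 11.69.
  set.seed(1)
  v <- c(100, 50, 10, rep(1, 7))
  U <- qr.Q(qr(matrix(rnorm(100), 10)))
  V <- qr.Q(qr(matrix(rnorm(200), 20)))[, 1:10]
  X <- U %*% diag(sqrt(v)) %*% t(V)
  dk <- determineK(X)
  expect_equal(dk$selection@K, 2L)
  expect_true(dk$selection@certified)
  expect_lte(dk$selection@kUsed, 4L)
  expect_equal(dk$selection@K, oracleK(X))
  expect_gte(dk$selection@overEstimate, dk$selection@underEstimate)
  ## a single informative component certifies K = 1 immediately
  X1 <- outer(rnorm(12), rnorm(30))
  dk1 <- determineK(X1)
  expect_equal(dk1$selection@K, 1L)
  expect_true(dk1$selection@certified)
})

test_that("certified K always equals the full-spectrum rule", {
  set.seed(31)
  for (i in 1:40) {
    s <- sample(10:40, 1); t <- sample(30:120, 1)
    X <- randomSpectrumMatrix(s, t, sample(c("flat", "steep", "mixed"), 1))
    dk <- determineK(X)
    expect_true(dk$selection@certified)
    expect_identical(dk$selection@K, as.integer(oracleK(X)))
  }
})

test_that("PCA normalization removes exactly the selected components", {
  set.seed(17)
  X <- randomSpectrumMatrix(15, 50, "steep")
  X <- sweep(X, 2, colMeans(X))
  dk <- determineK(X)
  sp <- dk$spectrum
  norm <- pcaNormalize(X, dk$selection, sp)
  K <- dk$selection@K
  expect_gt(K, 0L)
  for (j in seq_len(K))
    expect_lt(max(abs(norm %*% sp@v[, j])), 1e-8)
  ## equals the full-SVD reconstruction oracle
  sv <- svd(X)
  recon <- sv$u[, 1:K, drop = FALSE] %*%
    (sv$d[1:K] * t(sv$v[, 1:K, drop = FALSE]))
  expect_equal(norm, X - recon, tolerance = 1e-8)
  ## K = 0 is the identity; full rank removal annihilates a rank-1 matrix
  expect_identical(pcaNormalize(X, 0L, sp), X)
  r1 <- outer(rnorm(6), rnorm(20))
  sp1 <- truncatedSVD(r1, 1)
  expect_lt(max(abs(pcaNormalize(r1, 1L, sp1))), 1e-8)
})

test_that("post-normalization SD filter removes hyper-variable targets", {
  set.seed(23)
  d <- matrix(rnorm(10 * 20, 0, 1), 10, 20,
              dimnames = list(sprintf("S%02d", 1:10), NULL))
  planted <- c(4, 9, 13)
  d[, planted] <- rnorm(10 * 3, 0, 100)
  rdm <- ReadDepthMatrix(
    abs(d), parseTarget(sprintf("1:%d-%d", seq(1, by = 200, length.out = 20),
                                seq(100, by = 200, length.out = 20))))
  rdm@depths <- d; rdm@stage <- "pca_normalized"
  res <- filterTargetsPost(rdm)
  expect_equal(nrow(res$report), 3L)
  expect_equal(which(!targetStrings(targets(rdm)) %in%
                       targetStrings(targets(res$matrix))), planted)
  ## an all-zero matrix keeps everything
  z <- rdm; z@depths <- matrix(0, 10, 20, dimnames = dimnames(d))
  expect_equal(nrow(filterTargetsPost(z)$report), 0L)
})

.row3 <- function(vals) {
  m <- ReadDepthMatrix(
    matrix(rep(vals, 2), 2, byrow = TRUE,
           dimnames = list(c("r1", "r2"), NULL)),
    parseTarget(c("1:1-10", "1:20-30", "1:40-50")))
  m@stage <- "pca_normalized"
  m
}

test_that("z-scoring standardizes rows with the sample-SD convention", {
  rdm <- ReadDepthMatrix(
    matrix(c(1, 2, 3, 4, 4, 4), 2, byrow = TRUE,
           dimnames = list(c("a", "b"), NULL)),
    parseTarget(c("1:1-10", "1:20-30", "1:40-50")))
  rdm@stage <- "pca_normalized"
  expect_error(zscoreSamples(rdm), "sample 'b'")
  set.seed(12)
  good <- rdm
  good@depths <- matrix(rnorm(6 * 50), 6, 50,
                        dimnames = list(letters[1:6], NULL))
  good@targets <- parseTarget(sprintf("1:%d-%d",
                                      seq(1, by = 100, length.out = 50),
                                      seq(50, by = 100, length.out = 50)))
  z <- zscoreSamples(good)
  expect_lt(max(abs(rowMeans(depths(z)))), 1e-12)
  expect_lt(max(abs(apply(depths(z), 1, sd) - 1)), 1e-12)
  ## row (1, 2, 3): sample SD is exactly 1
  expect_equal(unname(depths(zscoreSamples(.row3(c(1, 2, 3))))[1, ]),
               c(-1, 0, 1))
})
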