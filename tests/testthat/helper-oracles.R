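## Independent oracles, written from first principles (no calls into the
## package code paths they check).

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Exhaustive 3^T path enumeration for the 3-state copy-number HMM.
## Transitions, emissions and the initial distribution are recomputed here
## from the model definition; distances are midpoint-to-midpoint with Inf
## at chromosome breaks.
oracleHMM <- function(z, targets, p = 1e-8, q = 1/6, D = 7e4, M = 3) {
  T_ <- length(z)
  chrom <- as.character(GenomeInfoDb::seqnames(targets))
  s <- GenomicRanges::start(targets)
  e <- GenomicRanges::end(targets)
  mid <- (s + e) / 2
  d <- if (T_ > 1L) pmax(mid[-1L] - mid[-T_], 0) else numeric(0)
  if (T_ > 1L) d[chrom[-1L] != chrom[-T_]] <- Inf
  T0 <- matrix(c(1 - q, q, 0, p, 1 - 2 * p, p, 0, q, 1 - q), 3, byrow = TRUE)
  Pi <- matrix(c(p, 1 - 2 * p, p), 3, 3, byrow = TRUE)
  trans <- lapply(d, function(dd) {
    f <- if (is.infinite(dd)) 0 else exp(-dd / D)
    f * T0 + (1 - f) * Pi
  })
  mu <- c(-M, 0, M)
  lem <- matrix(0, T_, 3)
  for (j in 1:3) lem[, j] <- stats::dnorm(z, mu[j], 1, log = TRUE)
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  lp <- log(c(p, 1 - 2 * p, p))[paths[, 1L]] + lem[1L, ][paths[, 1L]]
  if (T_ > 1L) {
    for (t in 2:T_) {
      lt <- log(trans[[t - 1L]])
      lp <- lp + lt[cbind(paths[, t - 1L], paths[, t])] +
        lem[t, ][paths[, t]]
    }
  }
  loglik <- logSumExp(lp)
  eventProb <- function(ind) {
    if (!any(ind)) return(0)
    exp(logSumExp(lp[ind]) - loglik)
  }
  callProbs <- function(a, b, c_) {
    inside <- paths[, a:b, drop = FALSE]
    pSome <- eventProb(apply(inside == c_, 1L, any))
    pNonDip <- eventProb(apply(inside != 2L, 1L, any))
    allC <- apply(inside == c_, 1L, all)
    leftOK <- if (a > 1L) paths[, a - 1L] != c_ else TRUE
    rightOK <- if (b < T_) paths[, b + 1L] != c_ else TRUE
    pExact <- eventProb(allC & leftOK & rightOK)
    pStart <- eventProb(paths[, a] == c_ & leftOK)
    pStop <- eventProb(paths[, b] == c_ & rightOK)
    c(P_EXACT = pExact, P_SOME = pSome, P_NON_DIPLOID = pNonDip,
      P_START = pStart, P_STOP = pStop)
  }
  list(loglik = loglik, path = unname(paths[which.max(lp), ]),
       callProbs = callProbs)
}

## Random short target chains with mixed spacing: chromosome breaks (Inf),
## duplicated intervals (midpoint distance 0), abutting, typical and huge
## gaps.
randomTargets <- function(T_) {
  chrom <- character(T_); starts <- numeric(T_); ends <- numeric(T_)
  cur <- 1L
  starts[1L] <- 1000; ends[1L] <- 1099; chrom[1L] <- "1"
  if (T_ > 1L) {
    for (i in 2:T_) {
      r <- stats::runif(1)
      if (r < 0.15) {
        cur <- cur + 1L
        starts[i] <- 1000; ends[i] <- 1099
      } else if (r < 0.3) {
        starts[i] <- starts[i - 1L]; ends[i] <- ends[i - 1L]
      } else if (r < 0.5) {
        starts[i] <- ends[i - 1L] + 1; ends[i] <- starts[i] + 99
      } else if (r < 0.85) {
        starts[i] <- ends[i - 1L] + sample(100:5000, 1)
        ends[i] <- starts[i] + 99
      } else {
        starts[i] <- ends[i - 1L] + 1e7; ends[i] <- starts[i] + 99
      }
      chrom[i] <- as.character(cur)
    }
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

## Full-spectrum rank-selection rule: K = #{ v_i >= coef * sum(v) / n }
## computed from the complete singular spectrum.
oracleK <- function(x, coef = 0.7) {
  v <- svd(x)$d^2
  n <- min(dim(x))
  sum(v >= coef * sum(v) / n)
}

## Random test matrices with flat, steep and mixed singular spectra.
randomSpectrumMatrix <- function(s, t, kind = c("flat", "steep", "mixed")) {
  kind <- match.arg(kind)
  m <- min(s, t)
  sv <- switch(kind,
    flat = stats::runif(m, 0.9, 1.1),
    steep = c(stats::runif(min(5L, m), 20, 100),
              stats::runif(max(0L, m - 5L), 0.01, 0.1)),
    mixed = 30 * 0.75^seq_len(m) + stats::runif(m, 0, 0.05))
  sv <- sort(sv, decreasing = TRUE)
  U <- qr.Q(qr(matrix(stats::rnorm(s * m), s)))
  V <- qr.Q(qr(matrix(stats::rnorm(t * m), t)))[, seq_len(m), drop = FALSE]
  U %*% (sv * t(V))
}

## Brute-force per-base coverage tally straight from SAM text. Applies the
## default filters (min MAPQ, no duplicates/secondary/supplementary) and
## counts CIGAR M/=/X bases, once per QNAME in fragment mode.
bruteCoverage <- function(samLines, targets, minMapQ = 20,
                          unit = c("fragment", "read")) {
  unit <- match.arg(unit)
  recs <- samLines[!startsWith(samLines, "@")]
  chromT <- as.character(GenomeInfoDb::seqnames(targets))
  st <- GenomicRanges::start(targets); en <- GenomicRanges::end(targets)
  covered <- list()  # per record: chrom, qname, positions
  for (line in recs) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L]); mapq <- as.integer(f[5L])
    if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 256L) > 0L ||
        bitwAnd(flag, 1024L) > 0L || bitwAnd(flag, 2048L) > 0L) next
    if (mapq < minMapQ) next
    ref <- as.integer(f[4L]); pos <- integer(0)
    ops <- regmatches(f[6L], gregexpr("[0-9]+[MIDNSHP=X]", f[6L]))[[1L]]
    for (o in ops) {
      n <- as.integer(sub("[A-Z=]$", "", o))
      op <- sub("^[0-9]+", "", o)
      if (op %in% c("M", "=", "X")) {
        pos <- c(pos, ref:(ref + n - 1L)); ref <- ref + n
      } else if (op %in% c("D", "N")) ref <- ref + n
    }
    covered[[length(covered) + 1L]] <-
      list(chrom = f[3L], qname = f[1L], pos = pos)
  }
  vapply(seq_along(targets), function(ti) {
    span <- st[ti]:en[ti]
    depth <- 0
    if (unit == "fragment") {
      byq <- split(covered, vapply(covered, `[[`, "", "qname"))
      for (grp in byq) {
        pos <- unique(unlist(lapply(
          Filter(function(r) r$chrom == chromT[ti], grp), `[[`, "pos")))
        depth <- depth + sum(pos %in% span)
      }
    } else {
      for (r in covered)
        if (r$chrom == chromT[ti]) depth <- depth + sum(r$pos %in% span)
    }
    depth / length(span)
  }, 0)
}

## Small annotated cohort used by several io/normalization tests.
smallCohort <- function(seed = 11, nSamples = 20, nTargets = 60,
                        batchRank = 2, cnvSpecs = NULL) {
  simulateCohort(simulationConfig(
    nSamples = nSamples, nTargets = nTargets, batchRank = batchRank,
    cnvSpecs = cnvSpecs, seed = seed))
}
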