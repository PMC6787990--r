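#' Configuration for a synthetic WES cohort
#'
#' Describes the generative model
#' `depth(s, t) = noise(base_t * scale_s * (1 + sum_r batch) * cnvFactor)`:
#' per-target baseline means drawn uniformly from `meanDepthRange`, mild
#' log-normal per-sample scale factors, a rank-`batchRank` multiplicative
#' batch structure built from orthogonalized factors (so the true low-rank
#' spectrum is known by construction), Poisson sampling noise with
#' read-count granularity, and embedded multi-target CNVs
#' (factor 0.5 = heterozygous deletion, 1.5 = duplication).
#'
#' @param nSamples,nTargets cohort dimensions.
#' @param targetLengthRange target length range in bp.
#' @param meanDepthRange per-target baseline mean depth range.
#' @param batchRank number of systematic-bias components (0 = none).
#' @param batchStrength scale of the multiplicative batch effect.
#' @param noiseModel `"poisson"` (default; mean-variance coupled, like
#'   sequencing depth), `"gaussian"`, or `"none"`.
#' @param cnvSpecs data.frame with columns `sample` (index or ID),
#'   `firstTarget`, `numTargets`, `factor`; `NULL` for none.
#' @param seed integer; identical seed gives identical outputs.
#' @param readLength read length used for Poisson count granularity.
#' @param nChrom number of chromosomes targets are spread over.
#' @return list of class `wescnv_simconfig`.
#' @export
simulationConfig <- function(nSamples, nTargets,
                             targetLengthRange = c(120, 300),
                             meanDepthRange = c(80, 150),
                             batchRank = 0L, batchStrength = 0.15,
                             noiseModel = c("poisson", "gaussian", "none"),
                             cnvSpecs = NULL, seed = 1L,
                             readLength = 100L, nChrom = 2L) {
  stopifnot(nSamples >= 1, nTargets >= 1, batchRank >= 0,
            all(targetLengthRange > 0), all(meanDepthRange > 0))
  if (!is.null(cnvSpecs)) {
    need <- c("sample", "firstTarget", "numTargets", "factor")
    if (!all(need %in% names(cnvSpecs)))
      stop("cnvSpecs needs columns: ", paste(need, collapse = ", "))
    if (any(cnvSpecs$factor <= 0)) stop("CNV factor must be > 0")
  }
  structure(list(
    nSamples = as.integer(nSamples), nTargets = as.integer(nTargets),
    targetLengthRange = targetLengthRange, meanDepthRange = meanDepthRange,
    batchRank = as.integer(batchRank), batchStrength = batchStrength,
    noiseModel = match.arg(noiseModel), cnvSpecs = cnvSpecs,
    seed = as.integer(seed), readLength = as.integer(readLength),
    nChrom = as.integer(nChrom)), class = "wescnv_simconfig")
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

#' Simulate a WES read-depth cohort with known structure
#'
#' All randomness flows from `config$seed`; the same config reproduces the
#' cohort bit for bit. Target annotations (GC 0.3--0.6, complexity
#' 0--0.05) are drawn inside the default passing ranges so that no target
#' is excluded unless the caller plants a violation.
#'
#' @param config a [simulationConfig()] object.
#' @return list with `matrix` (raw [ReadDepthMatrix-class], annotated
#'   targets), `truth` (data.frame, one row per embedded CNV), `expected`
#'   (the noiseless expected matrix) and `config`.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "wescnv_simconfig"))
  .withSeed(config$seed, {
    s <- config$nSamples; t <- config$nTargets
    ## targets spread evenly over chromosomes with irregular gaps
    perChrom <- diff(round(seq(0, t, length.out = config$nChrom + 1L)))
    chrom <- rep(as.character(seq_len(config$nChrom)), perChrom)
    len <- round(stats::runif(t, config$targetLengthRange[1L],
                              config$targetLengthRange[2L]))
    gaps <- round(stats::runif(t, 200, 2000))
    starts <- integer(t)
    pos <- 0L
    for (i in seq_len(t)) {
      if (i > 1L && chrom[i] != chrom[i - 1L]) pos <- 0L
      starts[i] <- pos + gaps[i]
      pos <- starts[i] + len[i] - 1L
    }
    tg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts,
                                                         width = len))
    GenomicRanges::mcols(tg)$gc <- stats::runif(t, 0.3, 0.6)
    GenomicRanges::mcols(tg)$complexity <- stats::runif(t, 0, 0.05)
    base <- stats::runif(t, config$meanDepthRange[1L],
                         config$meanDepthRange[2L])
    scale <- exp(stats::rnorm(s, 0, 0.05))
    mult <- matrix(1, s, t)
    if (config$batchRank > 0L) {
      A <- matrix(stats::rnorm(s * config$batchRank), s)
      ## orthogonalized target loadings rescaled to unit-variance entries,
      ## so each component perturbs every target at O(batchStrength)
      Q <- qr.Q(qr(matrix(stats::rnorm(t * config$batchRank), t))) * sqrt(t)
      mult <- pmax(1 + config$batchStrength * (A %*% t(Q)), 0.05)
    }
    cnvFactor <- matrix(1, s, t)
    ids <- sprintf("S%03d", seq_len(s))
    truth <- NULL
    if (!is.null(config$cnvSpecs) && nrow(config$cnvSpecs)) {
      sp <- config$cnvSpecs
      sidx <- if (is.numeric(sp$sample)) as.integer(sp$sample)
              else match(sp$sample, ids)
      first <- as.integer(sp$firstTarget)
      last <- first + as.integer(sp$numTargets) - 1L
      if (any(is.na(sidx)) || any(sidx < 1L) || any(sidx > s) ||
          any(first < 1L) || any(last > t))
        stop("CNV spec outside matrix bounds")
      for (i in seq_len(nrow(sp)))
        cnvFactor[sidx[i], first[i]:last[i]] <-
          cnvFactor[sidx[i], first[i]:last[i]] * sp$factor[i]
      truth <- data.frame(
        SAMPLE = ids[sidx],
        CNV = ifelse(sp$factor < 1, "DEL", "DUP"),
        CHR = chrom[first],
        START = starts[first], STOP = starts[last] + len[last] - 1L,
        INTERVAL = sprintf("%s:%d-%d", chrom[first], starts[first],
                           starts[last] + len[last] - 1L),
        NUM_TARG = as.integer(sp$numTargets),
        factor = sp$factor, firstTarget = first, lastTarget = last,
        stringsAsFactors = FALSE)
      if (any(chrom[first] != chrom[last]))
        stop("CNV spec spans a chromosome boundary")
    } else {
      truth <- data.frame(SAMPLE = character(), CNV = character(),
                          CHR = character(), START = integer(),
                          STOP = integer(), INTERVAL = character(),
                          NUM_TARG = integer(), factor = numeric(),
                          firstTarget = integer(), lastTarget = integer(),
                          stringsAsFactors = FALSE)
    }
    expected <- (scale %o% base) * mult * cnvFactor
    d <- switch(config$noiseModel,
      none = expected,
      poisson = {
        lambda <- expected * rep(len, each = s) / config$readLength
        matrix(stats::rpois(s * t, lambda), s, t) *
          config$readLength / rep(len, each = s)
      },
      gaussian = pmax(expected + stats::rnorm(s * t, 0, sqrt(expected)), 0))
    rownames(d) <- ids
    rownames(expected) <- ids
    list(matrix = ReadDepthMatrix(d, tg), truth = truth,
         expected = expected, config = config)
  })
}

#' Tiny SAM fixture with analytically known coverage
#'
#' Emits valid coordinate-sorted SAM text in which each target is covered by
#' an integer number of reads spanning it exactly, so the brute-force
#' per-base depth equals `depths` by construction. Optional crafted extras
#' exercise the coverage filters on the first target: a MAPQ-0 read and a
#' duplicate-flagged read (both ignored under default filters), and an
#' overlapping proper pair whose mates share the middle third of the target
#' (counted once per base in fragment mode, twice in read mode).
#'
#' @param targets `GRanges` of targets.
#' @param depths integer read depth per target (error if not integral).
#' @param extras character subset of `c("mapq0", "duplicate",
#'   "overlapping_mates")`.
#' @param sample sample name written to the read group.
#' @return list with `sam` (character vector of SAM lines),
#'   `expectedFragment` and `expectedRead` (mean coverage per target under
#'   default filters for each counting unit).
#' @export
simulateSamFixture <- function(targets, depths, extras = character(0),
                               sample = "SIM1") {
  if (length(depths) != length(targets))
    stop("one depth per target required")
  if (any(abs(depths - round(depths)) > 1e-9) || any(depths < 0))
    stop("impossible depth request: depths must be non-negative integers")
  depths <- as.integer(round(depths))
  if (length(extras))
    extras <- match.arg(extras, c("mapq0", "duplicate", "overlapping_mates"),
                        several.ok = TRUE)
  chrom <- as.character(GenomeInfoDb::seqnames(targets))
  starts <- GenomicRanges::start(targets)
  ends <- GenomicRanges::end(targets)
  len <- GenomicRanges::width(targets)
  rec <- function(qname, flag, rname, pos, mapq, cigar, rnext = "*",
                  pnext = 0L, tlen = 0L, seqlen) {
    paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
          strrep("A", seqlen), "*", "RG:Z:rg1", sep = "\t")
  }
  rows <- list(); posKey <- numeric(0); chrKey <- character(0)
  add <- function(line, chr, pos) {
    rows[[length(rows) + 1L]] <<- line
    chrKey[length(chrKey) + 1L] <<- chr
    posKey[length(posKey) + 1L] <<- pos
  }
  for (i in seq_along(targets)) {
    for (j in seq_len(depths[i]))
      add(rec(sprintf("t%d_r%d", i, j), 0L, chrom[i], starts[i], 60L,
              sprintf("%dM", len[i]), seqlen = len[i]),
          chrom[i], starts[i])
  }
  expectedFragment <- as.numeric(depths)
  expectedRead <- as.numeric(depths)
  if (length(extras) && length(targets)) {
    L <- len[1L]; s1 <- starts[1L]; e1 <- ends[1L]
    if ("mapq0" %in% extras)
      add(rec("xtra_mapq0", 0L, chrom[1L], s1, 0L, sprintf("%dM", L),
              seqlen = L), chrom[1L], s1)
    if ("duplicate" %in% extras)
      add(rec("xtra_dup", 1024L, chrom[1L], s1, 60L, sprintf("%dM", L),
              seqlen = L), chrom[1L], s1)
    if ("overlapping_mates" %in% extras) {
      ## mates cover [s1, s1+2L/3) and [s1+L/3, e1]: middle third overlaps
      l1 <- ceiling(2 * L / 3)
      p2 <- s1 + floor(L / 3)
      l2 <- e1 - p2 + 1L
      add(rec("xtra_pair", 99L, chrom[1L], s1, 60L, sprintf("%dM", l1),
              rnext = "=", pnext = p2, tlen = (p2 + l2 - s1),
              seqlen = l1), chrom[1L], s1)
      add(rec("xtra_pair", 147L, chrom[1L], p2, 60L, sprintf("%dM", l2),
              rnext = "=", pnext = s1, tlen = -(p2 + l2 - s1),
              seqlen = l2), chrom[1L], p2)
      expectedFragment[1L] <- expectedFragment[1L] + 1
      expectedRead[1L] <- expectedRead[1L] + (l1 + l2) / L
    }
  }
  chromOrder <- unique(chrom)
  ord <- order(match(chrKey, chromOrder), posKey)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d",
                      chromOrder,
                      vapply(chromOrder, function(cc)
                        max(ends[chrom == cc]) + 1000L, 1L)),
              sprintf("@RG\tID:rg1\tSM:%s", sample))
  list(sam = c(header, unlist(rows)[ord]),
       expectedFragment = expectedFragment, expectedRead = expectedRead)
}

#' End-to-end recovery experiment on a synthetic cohort
#'
#' Runs the full pipeline (filter, centre, rank selection, PCA
#' normalization, z-score, HMM discovery) on a simulated cohort and scores
#' the calls against the embedded truth: a truth CNV counts as recovered
#' when an overlap-matching call exists for the same sample and type, and
#' as accurately recovered when additionally both breakpoints are within
#' `maxBreakpointError` targets. Optionally repeats discovery with PCA
#' normalization skipped (`K = 0`) for a paired comparison.
#'
#' @param config a [simulationConfig()]; should embed CNVs.
#' @param thresholds a [FilterThresholds-class].
#' @param params an [HMMParameters-class].
#' @param comparePCA also run with normalization skipped.
#' @param maxBreakpointError breakpoint tolerance in targets (default 1).
#' @return list with recovery statistics (see details in the source):
#'   `nTruth`, `detected`, `detectionRate`, `accurate`, `accurateRate`,
#'   `breakpointErrors`, `falseCalls`, `K`, `calls`, plus `detectedNoPCA` /
#'   `callsNoPCA` when `comparePCA` is TRUE.
#' @export
recoveryExperiment <- function(config, thresholds = filterThresholds(),
                               params = hmmParameters(), comparePCA = TRUE,
                               maxBreakpointError = 1L) {
  sim <- simulateCohort(config)
  norm <- normalizeDepths(sim$matrix, thresholds)
  calls <- discoverCNVs(norm$z, norm$original, params)
  score <- function(calls, z) {
    tg <- targets(z)
    nTruth <- nrow(sim$truth)
    detected <- logical(nTruth); bpErr <- rep(NA_integer_, nTruth)
    for (i in seq_len(nTruth)) {
      tr <- sim$truth[i, ]
      cand <- which(calls$SAMPLE == tr$SAMPLE & calls$CNV == tr$CNV &
                    calls$CHR == tr$CHR &
                    calls$START <= tr$STOP & calls$STOP >= tr$START)
      if (!length(cand)) next
      detected[i] <- TRUE
      ## truth boundaries as indices into the filtered target list
      ov <- which(as.character(GenomeInfoDb::seqnames(tg)) == tr$CHR &
                  GenomicRanges::start(tg) <= tr$STOP &
                  GenomicRanges::end(tg) >= tr$START)
      idx <- do.call(rbind, lapply(strsplit(calls$TARGETS[cand],
                                            "..", fixed = TRUE),
                                   as.integer))
      err <- pmax(abs(idx[, 1L] - min(ov)), abs(idx[, 2L] - max(ov)))
      bpErr[i] <- min(err)
    }
    falsePos <- sum(!(seq_len(nrow(calls)) %in% unlist(lapply(
      seq_len(nTruth), function(i) {
        tr <- sim$truth[i, ]
        which(calls$SAMPLE == tr$SAMPLE & calls$CNV == tr$CNV &
              calls$CHR == tr$CHR &
              calls$START <= tr$STOP & calls$STOP >= tr$START)
      }))))
    list(detected = detected, bpErr = bpErr, falseCalls = falsePos)
  }
  sc <- score(calls, norm$z)
  out <- list(
    nTruth = nrow(sim$truth),
    detected = sum(sc$detected),
    detectionRate = mean(sc$detected),
    accurate = sum(sc$detected & !is.na(sc$bpErr) &
                   sc$bpErr <= maxBreakpointError),
    breakpointErrors = sc$bpErr,
    falseCalls = sc$falseCalls,
    K = norm$selection@K,
    calls = calls, truth = sim$truth, normalization = norm)
  out$accurateRate <- out$accurate / max(out$nTruth, 1L)
  if (comparePCA) {
    norm0 <- normalizeDepths(sim$matrix, thresholds, K = 0L)
    calls0 <- discoverCNVs(norm0$z, norm0$original, params)
    sc0 <- score(calls0, norm0$z)
    out$detectedNoPCA <- sum(sc0$detected)
    out$callsNoPCA <- calls0
  }
  out
}
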