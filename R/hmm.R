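#' Distance-dependent transition matrix
#'
#' `T(d) = f * T0 + (1 - f) * Pi` with `f = exp(-d / D)`, where `T0` is the
#' zero-distance transition matrix
#' `[[1-q, q, 0], [p, 1-2p, p], [0, q, 1-q]]` (state order DEL, DIP, DUP)
#' and `Pi` has every row equal to the CNV-start distribution
#' `(p, 1-2p, p)`. As the distance between consecutive targets grows, state
#' memory decays towards independence; `d = Inf` (a chromosome break) gives
#' exactly the stationary rows.
#'
#' @param d inter-target distance in bp (`>= 0`, may be `Inf`).
#' @param params an [HMMParameters-class].
#' @return 3x3 row-stochastic matrix with dimnames DEL/DIP/DUP.
#' @export
transitionMatrix <- function(d, params = hmmParameters()) {
  if (length(d) != 1L || is.na(d) || d < 0)
    stop("d must be a single non-negative distance (or Inf)")
  p <- params@p
  q <- 1 / params@meanTargetsPerCNV
  f <- if (is.infinite(d)) 0 else exp(-d / params@distanceScale)
  T0 <- matrix(c(1 - q, q,         0,
                 p,     1 - 2 * p, p,
                 0,     q,         1 - q),
               nrow = 3L, byrow = TRUE)
  Pi <- matrix(rep(c(p, 1 - 2 * p, p), each = 3L), nrow = 3L)
  out <- f * T0 + (1 - f) * Pi
  dimnames(out) <- list(.STATES, .STATES)
  out
}

#' Emission log-density of a z-score
#'
#' Unit-variance normal log densities with means `-M` (DEL), `0` (DIP),
#' `+M` (DUP), `M = emissionShift`.
#'
#' @param z numeric z-score(s).
#' @param state `"DEL"`, `"DIP"` or `"DUP"`.
#' @param params an [HMMParameters-class].
#' @return natural-log density, same length as `z`.
#' @export
emissionLogDensity <- function(z, state = c("DEL", "DIP", "DUP"),
                               params = hmmParameters()) {
  state <- match.arg(state)
  mu <- c(DEL = -params@emissionShift, DIP = 0,
          DUP = params@emissionShift)[[state]]
  stats::dnorm(z, mean = mu, sd = 1, log = TRUE)
}

## Per-sample HMM context: initial distribution, per-step transition
## matrices (linear scale) and emission density matrix (T x 3, linear).
.hmmContext <- function(z, targets, params) {
  T_ <- length(z)
  if (length(targets) != T_)
    stop("z-score vector length (", T_, ") != target count (",
         length(targets), ")")
  if (!all(is.finite(z))) stop("non-finite z-score")
  p <- params@p
  init <- c(p, 1 - 2 * p, p)
  d <- targetDistances(targets, params@distanceMode)
  trans <- lapply(d, transitionMatrix, params = params)
  mu <- c(-params@emissionShift, 0, params@emissionShift)
  emis <- vapply(1:3, function(s) stats::dnorm(z, mu[s], 1),
                 numeric(T_))
  emis <- matrix(emis, nrow = T_, ncol = 3L)
  list(init = init, trans = trans, emis = emis, T_ = T_)
}

## Scaled forward pass (Rabiner rescaling). `mask` is an optional T x 3
## logical matrix of allowed states; disallowed states are zeroed after the
## emission product, which turns the pass into a constrained likelihood.
.scaledForward <- function(ctx, mask = NULL) {
  T_ <- ctx$T_
  alpha <- matrix(0, T_, 3L)
  logScale <- numeric(T_)
  phi <- ctx$init * ctx$emis[1L, ]
  if (!is.null(mask)) phi[!mask[1L, ]] <- 0
  s <- sum(phi)
  if (s == 0) return(list(loglik = -Inf))
  alpha[1L, ] <- phi / s
  logScale[1L] <- log(s)
  for (t in seq_len(T_)[-1L]) {
    phi <- as.numeric(alpha[t - 1L, ] %*% ctx$trans[[t - 1L]]) *
      ctx$emis[t, ]
    if (!is.null(mask)) phi[!mask[t, ]] <- 0
    s <- sum(phi)
    if (s == 0) return(list(loglik = -Inf))
    alpha[t, ] <- phi / s
    logScale[t] <- log(s)
  }
  list(alpha = alpha, logScale = logScale, loglik = sum(logScale))
}

## Scaled backward pass sharing the forward scaling factors.
.scaledBackward <- function(ctx, logScale) {
  T_ <- ctx$T_
  beta <- matrix(0, T_, 3L)
  beta[T_, ] <- 1
  if (T_ >= 2L) {
    for (t in rev(seq_len(T_ - 1L))) {
      beta[t, ] <- as.numeric(ctx$trans[[t]] %*%
                                (ctx$emis[t + 1L, ] * beta[t + 1L, ])) /
        exp(logScale[t + 1L])
    }
  }
  beta
}

#' Scaled forward/backward recursions
#'
#' Forward variables are rescaled to sum to 1 at every target (the scaling
#' factors accumulate the log-likelihood), which keeps all arithmetic in
#' well-scaled double precision even on chains where the plain
#' probability-space recursion underflows to zero. Posteriors
#' `gamma[t, i] = P(state_t = i | z)` sum to 1 per target.
#'
#' @param z numeric z-scores for one sample, one per target.
#' @param targets sorted `GRanges`, same length as `z`.
#' @param params an [HMMParameters-class].
#' @return list with `alpha`, `beta` (scaled T x 3 matrices), `logScale`
#'   (per-target log scaling factors), `loglik` (their sum), `gamma`
#'   (posterior matrix) and the internal `context` reused by
#'   [callQualities()].
#' @export
forwardBackward <- function(z, targets, params = hmmParameters()) {
  ctx <- .hmmContext(z, targets, params)
  fwd <- .scaledForward(ctx)
  if (!is.finite(fwd$loglik))
    stop("forward pass underflowed to zero probability")
  beta <- .scaledBackward(ctx, fwd$logScale)
  gamma <- fwd$alpha * beta
  gamma <- gamma / rowSums(gamma)
  colnames(gamma) <- .STATES
  list(alpha = fwd$alpha, beta = beta, logScale = fwd$logScale,
       loglik = fwd$loglik, gamma = gamma, context = ctx)
}

#' HMM log-likelihood by three routes
#'
#' `"scaled"` is the production route (per-target rescaling). `"logsumexp"`
#' runs the forward recursion entirely in log space with the log-sum-exp
#' reduction. `"naive"` is the textbook probability-space recursion with no
#' protection, provided to demonstrate underflow on long informative chains;
#' it returns `-Inf` when the recursion hits exact zero.
#'
#' @inheritParams forwardBackward
#' @param method one of `"scaled"`, `"logsumexp"`, `"naive"`.
#' @return log-likelihood (natural log).
#' @export
hmmLogLikelihood <- function(z, targets, params = hmmParameters(),
                             method = c("scaled", "logsumexp", "naive")) {
  method <- match.arg(method)
  ctx <- .hmmContext(z, targets, params)
  if (method == "scaled")
    return(.scaledForward(ctx)$loglik)
  if (method == "naive") {
    a <- ctx$init * ctx$emis[1L, ]
    for (t in seq_len(ctx$T_)[-1L])
      a <- as.numeric(a %*% ctx$trans[[t - 1L]]) * ctx$emis[t, ]
    return(log(sum(a)))
  }
  ## log-sum-exp forward
  logEmis <- log(ctx$emis)
  la <- log(ctx$init) + logEmis[1L, ]
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  for (t in seq_len(ctx$T_)[-1L]) {
    lt <- log(ctx$trans[[t - 1L]])
    la <- vapply(1:3, function(j) lse(la + lt[, j]), 0) + logEmis[t, ]
  }
  lse(la)
}

#' Viterbi decoding in log space
#'
#' Maximum a-posteriori state path under the initial distribution
#' `(p, 1-2p, p)`, the distance-dependent transitions and the normal
#' emission model. Max-product in natural-log space needs no rescaling.
#'
#' @inheritParams forwardBackward
#' @return list with `states` (character vector over DEL/DIP/DUP),
#'   `stateIdx` (integer codes 1/2/3) and `logProb` (joint log probability
#'   of path and data).
#' @export
viterbiPath <- function(z, targets, params = hmmParameters()) {
  ctx <- .hmmContext(z, targets, params)
  T_ <- ctx$T_
  logEmis <- log(ctx$emis)
  delta <- matrix(-Inf, T_, 3L)
  psi <- matrix(0L, T_, 3L)
  delta[1L, ] <- log(ctx$init) + logEmis[1L, ]
  for (t in seq_len(T_)[-1L]) {
    lt <- log(ctx$trans[[t - 1L]])
    for (j in 1:3) {
      cand <- delta[t - 1L, ] + lt[, j]
      psi[t, j] <- which.max(cand)
      delta[t, j] <- cand[psi[t, j]] + logEmis[t, j]
    }
  }
  states <- integer(T_)
  states[T_] <- which.max(delta[T_, ])
  if (T_ >= 2L)
    for (t in rev(seq_len(T_ - 1L)))
      states[t] <- psi[t + 1L, states[t + 1L]]
  list(states = .STATES[states], stateIdx = states,
       logProb = max(delta[T_, ]))
}

#' Candidate calls from a decoded state path
#'
#' Maximal runs of DEL and of DUP become candidate calls; DIP runs produce
#' nothing. Runs never span a chromosome boundary in the target list.
#'
#' @param stateIdx integer state codes (1 = DEL, 2 = DIP, 3 = DUP), one per
#'   target.
#' @param targets sorted `GRanges`, same length.
#' @return data.frame with columns `type`, `first`, `last` (1-based target
#'   indices, inclusive).
#' @export
segmentPath <- function(stateIdx, targets) {
  if (length(stateIdx) != length(targets))
    stop("state path length != target count")
  chrom <- as.character(GenomeInfoDb::seqnames(targets))
  ## break runs at chromosome changes by tagging states with a chrom block
  block <- cumsum(c(TRUE, chrom[-1L] != chrom[-length(chrom)]))
  r <- rle(paste(stateIdx, block))
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  st <- stateIdx[firsts]
  keep <- st != 2L
  data.frame(type = .STATES[st[keep]], first = firsts[keep],
             last = ends[keep], stringsAsFactors = FALSE)
}

#' Phred-scale a probability
#'
#' `phred(P) = round(-10 * log10(1 - P))` with round-half-up, clamped to
#' \[0, 99\].
#'
#' @param p probability (vector) of the event being true.
#' @return integer phred score(s) in \[0, 99\].
#' @export
phredQuality <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  q <- -10 * log10(1 - p)
  q[p >= 1] <- Inf
  as.integer(pmin(pmax(floor(q + 0.5), 0), 99))
}

#' The five phred-scaled call qualities
#'
#' For a candidate call of state `c` on the target interval `[a, b]`, each
#' probability is an exact ratio of a constrained to the unconstrained
#' chain likelihood, computed by scaled forward passes in which disallowed
#' states are zeroed at specific targets:
#' \describe{
#'   \item{Q_SOME}{`P(some target in [a, b] has state c)` = 1 minus the
#'     pass with state `c` forbidden throughout `[a, b]`.}
#'   \item{Q_EXACT}{`P(all of [a, b] in state c, flanked by non-c)`: only
#'     `c` allowed inside, `c` forbidden at `a - 1` and `b + 1` when those
#'     targets exist (the flanking constraint is dropped at chromosome-edge
#'     targets).}
#'   \item{Q_NON_DIPLOID}{`P(some target in [a, b] is not DIP)` = 1 minus
#'     the pass with only DIP allowed in `[a, b]`.}
#'   \item{Q_START}{`P(state c starts exactly at a)`: `c` forbidden at
#'     `a - 1` (if it exists), only `c` allowed at `a`.}
#'   \item{Q_STOP}{symmetric at `b`.}
#' }
#'
#' @param first,last 1-based inclusive target indices of the call.
#' @param type `"DEL"` or `"DUP"`.
#' @param fb result of [forwardBackward()] on the same sample and targets.
#' @return list with `probabilities` (named numeric, P_EXACT/P_SOME/
#'   P_NON_DIPLOID/P_START/P_STOP) and `phred` (named integer qualities).
#' @export
callQualities <- function(first, last, type, fb) {
  ctx <- fb$context
  T_ <- ctx$T_
  if (first < 1L || last > T_ || first > last)
    stop("call interval [", first, ", ", last, "] outside 1..", T_)
  c_ <- match(type, .STATES)
  if (is.na(c_) || c_ == 2L) stop("call type must be DEL or DUP")
  L <- fb$loglik
  constrained <- function(mask) {
    ll <- .scaledForward(ctx, mask)$loglik
    if (is.finite(ll)) exp(ll - L) else 0
  }
  freeMask <- function() matrix(TRUE, T_, 3L)
  inside <- first:last
  ## P_SOME: complement of "no target inside carries state c"
  m <- freeMask(); m[inside, c_] <- FALSE
  pSome <- 1 - constrained(m)
  ## P_NON_DIPLOID: complement of "all targets inside are DIP"
  m <- freeMask(); m[inside, -2L] <- FALSE
  pNonDip <- 1 - constrained(m)
  ## P_EXACT: all inside are c, flanks (when present) are not c
  m <- freeMask(); m[inside, -c_] <- FALSE
  if (first > 1L) m[first - 1L, c_] <- FALSE
  if (last < T_) m[last + 1L, c_] <- FALSE
  pExact <- constrained(m)
  ## P_START / P_STOP: breakpoint posteriors
  m <- freeMask(); m[first, -c_] <- FALSE
  if (first > 1L) m[first - 1L, c_] <- FALSE
  pStart <- constrained(m)
  m <- freeMask(); m[last, -c_] <- FALSE
  if (last < T_) m[last + 1L, c_] <- FALSE
  pStop <- constrained(m)
  probs <- c(P_EXACT = pExact, P_SOME = pSome, P_NON_DIPLOID = pNonDip,
             P_START = pStart, P_STOP = pStop)
  phred <- phredQuality(probs)
  names(phred) <- sub("^P_", "Q_", names(probs))
  list(probabilities = probs, phred = phred)
}

.emptyCalls <- function() {
  data.frame(SAMPLE = character(), CNV = character(), INTERVAL = character(),
             KB = numeric(), CHR = character(), MID_BP = numeric(),
             TARGETS = character(), NUM_TARG = integer(),
             Q_EXACT = integer(), Q_SOME = integer(),
             Q_NON_DIPLOID = integer(), Q_START = integer(),
             Q_STOP = integer(), MEAN_RD = numeric(),
             MEAN_ORIG_RD = numeric(), START = numeric(), STOP = numeric(),
             stringsAsFactors = FALSE)
}

#' Discover CNVs across a cohort
#'
#' Per sample, independently: Viterbi decoding, segmentation into candidate
#' DEL/DUP runs, and the five constrained-pass qualities; candidates with
#' `Q_SOME` below `params@minSomeQuality` (default 30) are suppressed. The
#' result is independent of sample processing order.
#'
#' @param z z-scored [ReadDepthMatrix-class] (stage `"zscored"`).
#' @param original [ReadDepthMatrix-class] of original (pre-normalization)
#'   depths aligned to `z`, used for `MEAN_ORIG_RD`; pass `NULL` to report
#'   `NA`.
#' @param params an [HMMParameters-class].
#' @return data.frame of calls in .xcnv column order (plus numeric `START`
#'   and `STOP` convenience columns); zero rows when nothing is called.
#' @export
discoverCNVs <- function(z, original = NULL, params = hmmParameters()) {
  tg <- targets(z)
  zd <- depths(z)
  od <- if (!is.null(original)) depths(original) else NULL
  if (!is.null(od) && !identical(dim(od), dim(zd)))
    stop("original matrix not aligned with z matrix")
  chrom <- as.character(GenomeInfoDb::seqnames(tg))
  starts <- GenomicRanges::start(tg)
  stops <- GenomicRanges::end(tg)
  out <- list()
  for (si in seq_len(nrow(zd))) {
    zrow <- zd[si, ]
    vit <- viterbiPath(zrow, tg, params)
    runs <- segmentPath(vit$stateIdx, tg)
    if (!nrow(runs)) next
    fb <- forwardBackward(zrow, tg, params)
    for (ri in seq_len(nrow(runs))) {
      a <- runs$first[ri]; b <- runs$last[ri]
      qual <- callQualities(a, b, runs$type[ri], fb)$phred
      if (qual[["Q_SOME"]] < params@minSomeQuality) next
      span <- stops[b] - starts[a] + 1
      out[[length(out) + 1L]] <- data.frame(
        SAMPLE = rownames(zd)[si], CNV = runs$type[ri],
        INTERVAL = sprintf("%s:%d-%d", chrom[a], starts[a], stops[b]),
        KB = span / 1000, CHR = chrom[a],
        MID_BP = (starts[a] + stops[b]) / 2,
        TARGETS = sprintf("%d..%d", a, b), NUM_TARG = b - a + 1L,
        Q_EXACT = qual[["Q_EXACT"]], Q_SOME = qual[["Q_SOME"]],
        Q_NON_DIPLOID = qual[["Q_NON_DIPLOID"]],
        Q_START = qual[["Q_START"]], Q_STOP = qual[["Q_STOP"]],
        MEAN_RD = mean(zrow[a:b]),
        MEAN_ORIG_RD = if (is.null(od)) NA_real_ else mean(od[si, a:b]),
        START = starts[a], STOP = stops[b],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.emptyCalls())
  do.call(rbind, out)
}

.XCNV_COLS <- c("SAMPLE", "CNV", "INTERVAL", "KB", "CHR", "MID_BP",
                "TARGETS", "NUM_TARG", "Q_EXACT", "Q_SOME", "Q_NON_DIPLOID",
                "Q_START", "Q_STOP", "MEAN_RD", "MEAN_ORIG_RD")

#' Write calls as an .xcnv table
#'
#' Tab-delimited with the canonical 15-column header. `KB`, `MEAN_RD` and
#' `MEAN_ORIG_RD` are printed with 2 decimals; `MID_BP` prints `.5` halves
#' only when present.
#'
#' @param calls data.frame from [discoverCNVs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXcnv <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.XCNV_COLS, collapse = "\t"), con)
  if (nrow(calls)) {
    midbp <- ifelse(calls$MID_BP %% 1 == 0,
                    sprintf("%.0f", calls$MID_BP),
                    sprintf("%.1f", calls$MID_BP))
    for (i in seq_len(nrow(calls))) {
      writeLines(paste(c(
        calls$SAMPLE[i], calls$CNV[i], calls$INTERVAL[i],
        sprintf("%.2f", calls$KB[i]), calls$CHR[i], midbp[i],
        calls$TARGETS[i], calls$NUM_TARG[i],
        calls$Q_EXACT[i], calls$Q_SOME[i], calls$Q_NON_DIPLOID[i],
        calls$Q_START[i], calls$Q_STOP[i],
        sprintf("%.2f", calls$MEAN_RD[i]),
        sprintf("%.2f", calls$MEAN_ORIG_RD[i])), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname writeXcnv
#' @export
readXcnv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    out <- .emptyCalls()
    return(out[, c(.XCNV_COLS, "START", "STOP")])
  }
  gr <- parseTarget(tab$INTERVAL)
  tab$START <- GenomicRanges::start(gr)
  tab$STOP <- GenomicRanges::end(gr)
  tab
}

#' Concordance between two call sets
#'
#' Each call in `setA` is classified against `setB`: an exact match shares
#' sample, type and both breakpoints; an overlap match shares sample and
#' type with an overlapping interval but different breakpoints; otherwise
#' it is unmatched. For matched pairs the absolute difference in target
#' count is reported (best-overlapping partner when several overlap).
#'
#' @param setA,setB call data.frames (from [discoverCNVs()] or
#'   [readXcnv()]).
#' @return list with counts `nA`, `nB`, `exact`, `overlap`, `unmatched` and
#'   a `pairs` data.frame (one row per matched call in `setA`, with `match`
#'   class and `targetDiff`).
#' @export
matchCalls <- function(setA, setB) {
  cls <- character(nrow(setA))
  diffs <- rep(NA_integer_, nrow(setA))
  for (i in seq_len(nrow(setA))) {
    cand <- which(setB$SAMPLE == setA$SAMPLE[i] &
                  setB$CNV == setA$CNV[i] &
                  setB$CHR == setA$CHR[i])
    if (!length(cand)) { cls[i] <- "unmatched"; next }
    exact <- cand[setB$START[cand] == setA$START[i] &
                  setB$STOP[cand] == setA$STOP[i]]
    if (length(exact)) {
      cls[i] <- "exact"
      diffs[i] <- abs(setB$NUM_TARG[exact[1L]] - setA$NUM_TARG[i])
      next
    }
    ovw <- pmin(setB$STOP[cand], setA$STOP[i]) -
      pmax(setB$START[cand], setA$START[i]) + 1
    hit <- cand[ovw > 0]
    if (!length(hit)) { cls[i] <- "unmatched"; next }
    best <- hit[which.max(ovw[ovw > 0])]
    cls[i] <- "overlap"
    diffs[i] <- abs(setB$NUM_TARG[best] - setA$NUM_TARG[i])
  }
  matched <- cls != "unmatched"
  list(nA = nrow(setA), nB = nrow(setB),
       exact = sum(cls == "exact"), overlap = sum(cls == "overlap"),
       unmatched = sum(cls == "unmatched"),
       pairs = data.frame(index = which(matched), match = cls[matched],
                          targetDiff = diffs[matched],
                          stringsAsFactors = FALSE))
  }
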