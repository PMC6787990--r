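#' Pre-normalization target filtering
#'
#' Removes targets failing any enabled rule: length outside
#' \[`minTargetLength`, `maxTargetLength`\], cohort mean depth outside
#' \[`minTargetMeanRD`, `maxTargetMeanRD`\], GC fraction outside
#' \[`minGC`, `maxGC`\] or complexity fraction above `maxComplexity` (GC and
#' complexity rules fire only where the annotation metadata columns are
#' present and non-missing).
#'
#' @param object a raw [ReadDepthMatrix-class].
#' @param thresholds a [FilterThresholds-class].
#' @return list with `matrix` (filtered `ReadDepthMatrix`) and `report`
#'   (data.frame of excluded targets and the comma-joined rules that fired).
#' @export
filterTargets <- function(object, thresholds = filterThresholds()) {
  tg <- targets(object)
  d <- depths(object)
  len <- GenomicRanges::width(tg)
  meanRD <- colMeans(d)
  reasons <- vector("list", length(tg))
  add <- function(which, label) {
    for (i in which) reasons[[i]] <<- c(reasons[[i]], label)
  }
  add(which(len < thresholds@minTargetLength |
            len > thresholds@maxTargetLength), "length")
  add(which(meanRD < thresholds@minTargetMeanRD |
            meanRD > thresholds@maxTargetMeanRD), "mean_rd")
  mc <- GenomicRanges::mcols(tg)
  if (!is.null(mc$gc))
    add(which(!is.na(mc$gc) &
              (mc$gc < thresholds@minGC | mc$gc > thresholds@maxGC)), "gc")
  if (!is.null(mc$complexity))
    add(which(!is.na(mc$complexity) &
              mc$complexity > thresholds@maxComplexity), "complexity")
  bad <- which(vapply(reasons, length, 1L) > 0L)
  if (length(bad) == length(tg))
    stop("all ", length(tg), " targets excluded by pre-filters")
  report <- data.frame(
    target = targetStrings(tg)[bad],
    reasons = vapply(reasons[bad], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  keep <- setdiff(seq_along(tg), bad)
  list(matrix = .subsetRDM(object, targetIdx = keep), report = report)
}

#' Sample filtering by depth statistics
#'
#' Removes samples whose mean depth over targets is outside
#' \[`minSampleMeanRD`, `maxSampleMeanRD`\] or whose depth standard deviation
#' exceeds `maxSampleSdRD`.
#'
#' @inheritParams filterTargets
#' @return list with `matrix` and `report` (sample, reasons).
#' @export
filterSamples <- function(object, thresholds = filterThresholds()) {
  d <- depths(object)
  m <- rowMeans(d)
  s <- apply(d, 1L, stats::sd)
  reasons <- vector("list", nrow(d))
  low <- which(m < thresholds@minSampleMeanRD |
               m > thresholds@maxSampleMeanRD)
  for (i in low) reasons[[i]] <- c(reasons[[i]], "mean_rd")
  hi <- which(s > thresholds@maxSampleSdRD)
  for (i in hi) reasons[[i]] <- c(reasons[[i]], "sd_rd")
  bad <- which(vapply(reasons, length, 1L) > 0L)
  if (length(bad) == nrow(d))
    stop("all ", nrow(d), " samples excluded by filters")
  report <- data.frame(
    sample = rownames(d)[bad],
    reasons = vapply(reasons[bad], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(nrow(d)), bad)
  list(matrix = .subsetRDM(object, samples = keep), report = report)
}

#' Mean-centre every target column
#'
#' Subtracts the cohort mean depth from each target column, the input to the
#' singular value decomposition. The uncentred matrix should be retained by
#' the caller for later `MEAN_ORIG_RD` reporting.
#'
#' @param object a filtered [ReadDepthMatrix-class] with at least 2 samples.
#' @return A `ReadDepthMatrix` at stage `"filtered_centered"` whose column
#'   means are 0.
#' @export
centerTargets <- function(object) {
  d <- depths(object)
  if (nrow(d) < 2L)
    stop("centering requires at least 2 samples; got ", nrow(d))
  d <- sweep(d, 2L, colMeans(d), "-")
  out <- .subsetRDM(object)
  out@depths <- d
  .advanceStage(out, "filtered_centered")
}

#' Top-k singular triples of a centred matrix
#'
#' Returns the leading `k` singular values/vectors with component variances
#' `v_i = sigma_i^2` in non-increasing order. The decomposition is LAPACK's
#' deterministic dense SVD truncated to `k` components; `n`, the number of
#' candidate components of the full decomposition, is `min(s, t)`.
#'
#' @param centered numeric matrix or centred `ReadDepthMatrix`.
#' @param k number of components, `1 <= k <= min(s, t)`.
#' @return An [SVDSpectrum-class].
#' @export
truncatedSVD <- function(centered, k) {
  x <- if (is(centered, "ReadDepthMatrix")) depths(centered) else centered
  n <- min(dim(x))
  if (k < 1L || k > n)
    stop("k must be in [1, ", n, "]; got ", k)
  sv <- svd(x, nu = k, nv = k)
  new("SVDSpectrum", variances = sv$d[seq_len(k)]^2,
      k = as.integer(k), n = as.integer(n),
      u = sv$u, d = sv$d[seq_len(k)], v = sv$v)
}

## rule on a (possibly truncated) spectrum given a total-variance estimate
.countAboveCutoff <- function(v, totalVar, n, coefficient) {
  sum(v >= coefficient * totalVar / n)
}

#' Choose K components to remove by the iterative truncated-SVD rule
#'
#' The full-spectrum rule removes every component whose variance satisfies
#' `v_i >= coefficient * sum(v) / n` (coefficient 0.7 by default). Computing
#' all `n` components is wasteful because in practice `K << n`; instead, the
#' total variance is bracketed from a truncated spectrum of `k` components:
#' the over-estimate is `sum(v_1..v_k) + (n - k - 1) * v_k` (the unseen tail
#' bounded by the smallest computed variance; the centred matrix has at most
#' `n - 1` informative components) and the under-estimate is `sum(v_1..v_k)`
#' (unseen tail taken as 0). `K` counts the computed components at or above
#' the cutoff derived from the over-estimate. When the first retained
#' component, `v_{K+1}`, falls below the cutoff derived from the
#' under-estimate, the result provably equals the full-spectrum `K` and is
#' certified. Otherwise `k` is doubled (up to `min(s,t) - 1`) and the
#' decomposition repeated; at the cap the exact full-spectrum rule is
#' applied directly.
#'
#' @param centered centred matrix or `ReadDepthMatrix`.
#' @param varianceCoefficient relative-variance coefficient (default 0.7).
#' @param initialKFraction first `k` as a fraction of `n` (default 0.1).
#' @return list with `selection` (a [RankSelection-class]) and `spectrum`
#'   (the [SVDSpectrum-class] that certified it, containing at least `K`
#'   singular triples for use by [pcaNormalize()]).
#' @export
determineK <- function(centered, varianceCoefficient = 0.7,
                       initialKFraction = 0.1) {
  x <- if (is(centered, "ReadDepthMatrix")) depths(centered) else centered
  n <- min(dim(x))
  kMax <- max(1L, n - 1L)
  k <- min(max(1L, as.integer(ceiling(initialKFraction * n))), kMax)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    spec <- truncatedSVD(x, k)
    v <- spec@variances
    if (!all(is.finite(v))) stop("non-finite component variances")
    over <- sum(v) + (n - k - 1) * v[k]
    under <- sum(v)
    K <- .countAboveCutoff(v, over, n, varianceCoefficient)
    cutoffUnder <- varianceCoefficient * under / n
    if (K < k && v[K + 1L] < cutoffUnder) {
      sel <- new("RankSelection", K = as.integer(K),
                 varianceCoefficient = varianceCoefficient,
                 initialKFraction = initialKFraction,
                 overEstimate = over, underEstimate = under,
                 certified = TRUE, kUsed = as.integer(k),
                 iterations = iter)
      return(list(selection = sel, spectrum = spec))
    }
    if (k >= kMax) {
      ## exact fallback: full spectrum, exact rule
      full <- truncatedSVD(x, n)
      vf <- full@variances
      total <- sum(vf)
      K <- .countAboveCutoff(vf, total, n, varianceCoefficient)
      sel <- new("RankSelection", K = as.integer(K),
                 varianceCoefficient = varianceCoefficient,
                 initialKFraction = initialKFraction,
                 overEstimate = total, underEstimate = total,
                 certified = TRUE, kUsed = as.integer(n),
                 iterations = iter + 1L)
      return(list(selection = sel, spectrum = full))
    }
    k <- min(2L * k, kMax)
  }
}

#' Remove the top K principal components
#'
#' Subtracts the rank-`K` reconstruction built from the leading singular
#' triples, so the output has (numerically) zero projection onto every
#' removed component. With `K = 0` the input is returned unchanged.
#'
#' @param centered centred `ReadDepthMatrix` (or matrix).
#' @param selection a [RankSelection-class] (or a bare integer `K`).
#' @param spectrum an [SVDSpectrum-class] holding at least `K` triples of
#'   the same matrix.
#' @return Object of the same kind as `centered`, stage `"pca_normalized"`.
#' @export
pcaNormalize <- function(centered, selection, spectrum) {
  K <- if (is(selection, "RankSelection")) selection@K else as.integer(selection)
  isRDM <- is(centered, "ReadDepthMatrix")
  x <- if (isRDM) depths(centered) else centered
  if (K > 0L) {
    if (K > spectrum@k)
      stop("K = ", K, " exceeds the ", spectrum@k, " available components")
    u <- spectrum@u[, seq_len(K), drop = FALSE]
    v <- spectrum@v[, seq_len(K), drop = FALSE]
    x <- x - u %*% (spectrum@d[seq_len(K)] * t(v))
  }
  if (!isRDM) return(x)
  out <- .subsetRDM(centered)
  out@depths <- x
  .advanceStage(out, "pca_normalized")
}

#' Post-normalization target filtering
#'
#' Removes targets whose column standard deviation in the PCA-normalized
#' matrix exceeds `maxTargetSdPost` (hyper-variable targets the
#' normalization could not stabilize).
#'
#' @inheritParams filterTargets
#' @export
filterTargetsPost <- function(object, thresholds = filterThresholds()) {
  d <- depths(object)
  s <- apply(d, 2L, stats::sd)
  bad <- which(s > thresholds@maxTargetSdPost)
  if (length(bad) == ncol(d))
    stop("all targets removed by post-normalization SD filter")
  report <- data.frame(
    target = targetStrings(targets(object))[bad],
    reasons = rep("sd_post", length(bad)),
    stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(ncol(d)), bad)
  list(matrix = .subsetRDM(object, targetIdx = keep), report = report)
}

#' Per-sample z-scores
#'
#' Standardizes each sample row to mean 0 and standard deviation 1 (sample
#' SD, denominator `t - 1`). These z-scores are the HMM's emission
#' observable.
#'
#' @param object normalized `ReadDepthMatrix`.
#' @return A `ReadDepthMatrix` at stage `"zscored"`.
#' @export
zscoreSamples <- function(object) {
  d <- depths(object)
  m <- rowMeans(d)
  s <- apply(d, 1L, stats::sd)
  zero <- which(s == 0)
  if (length(zero))
    stop("zero depth standard deviation for sample '",
         rownames(d)[zero[1L]], "'; cannot z-score")
  d <- (d - m) / s
  out <- .subsetRDM(object)
  out@depths <- d
  .advanceStage(out, "zscored")
}

#' Full normalization pipeline
#'
#' Chains [filterTargets()], [filterSamples()], [centerTargets()],
#' [determineK()], [pcaNormalize()], [filterTargetsPost()] and
#' [zscoreSamples()], keeping the original (uncentred, filtered) depths
#' aligned with the final target list for `MEAN_ORIG_RD` reporting.
#'
#' @param object raw [ReadDepthMatrix-class].
#' @param thresholds a [FilterThresholds-class].
#' @param varianceCoefficient,initialKFraction passed to [determineK()].
#' @param K optional fixed component count overriding [determineK()]
#'   (`K = 0` skips PCA normalization entirely).
#' @return list with `z` (z-scored matrix), `original` (filtered raw depths
#'   aligned to `z`), `selection`, `spectrum`, and `reports` (per-stage
#'   exclusion data.frames).
#' @export
normalizeDepths <- function(object, thresholds = filterThresholds(),
                            varianceCoefficient = 0.7,
                            initialKFraction = 0.1, K = NULL) {
  ft <- filterTargets(object, thresholds)
  fs <- filterSamples(ft$matrix, thresholds)
  filtered <- fs$matrix
  centered <- centerTargets(filtered)
  if (is.null(K)) {
    dk <- determineK(centered, varianceCoefficient, initialKFraction)
    selection <- dk$selection; spectrum <- dk$spectrum
  } else {
    K <- as.integer(K)
    spectrum <- if (K > 0L) truncatedSVD(centered, K) else NULL
    selection <- new("RankSelection", K = K,
                     varianceCoefficient = varianceCoefficient,
                     initialKFraction = initialKFraction,
                     overEstimate = NA_real_, underEstimate = NA_real_,
                     certified = FALSE, kUsed = K, iterations = 0L)
  }
  normalized <- pcaNormalize(centered, selection, spectrum)
  fp <- filterTargetsPost(normalized, thresholds)
  z <- zscoreSamples(fp$matrix)
  keptTargets <- match(targetStrings(targets(z)),
                       targetStrings(targets(filtered)))
  original <- .subsetRDM(filtered, targetIdx = keptTargets)
  list(z = z, original = original, selection = selection,
       spectrum = spectrum,
       reports = list(targets_pre = ft$report, samples = fs$report,
                      targets_post = fp$report))
}
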