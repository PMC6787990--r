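#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

.STAGES <- c("raw", "filtered_centered", "pca_normalized", "zscored")

#' Read-depth matrix for an exome cohort
#'
#' The central container of the package: an `s` samples by `t` targets matrix
#' of mean per-base read depth, with sample identifiers as row names and the
#' exome capture targets as a [GenomicRanges::GRanges] (1-based inclusive
#' coordinates, optionally annotated with `gc` and `complexity` metadata
#' columns). A `stage` label tracks the position of the payload in the
#' normalization pipeline; depths are constrained to be non-negative only at
#' the `"raw"` stage (centred and z-scored values may be negative).
#'
#' @slot depths numeric matrix, samples in rows, targets in columns.
#' @slot targets `GRanges` of capture targets, sorted by (chromosome, start).
#' @slot stage one of `"raw"`, `"filtered_centered"`, `"pca_normalized"`,
#'   `"zscored"`.
#'
#' @aliases ReadDepthMatrix-class
#' @exportClass ReadDepthMatrix
setClass("ReadDepthMatrix",
  representation(depths = "matrix", targets = "GRanges", stage = "character"))

setValidity("ReadDepthMatrix", function(object) {
  msg <- character()
  d <- object@depths
  tg <- object@targets
  if (!is.numeric(d))
    msg <- c(msg, "depths must be a numeric matrix")
  if (ncol(d) != length(tg))
    msg <- c(msg, sprintf("ncol(depths) [%d] != length(targets) [%d]",
                          ncol(d), length(tg)))
  if (is.null(rownames(d)) && nrow(d) > 0)
    msg <- c(msg, "depths must have sample identifiers as rownames")
  if (anyDuplicated(rownames(d)))
    msg <- c(msg, "duplicate sample identifiers")
  if (length(d) && !all(is.finite(d)))
    msg <- c(msg, "depths contains non-finite values")
  if (!(length(object@stage) == 1L && object@stage %in% .STAGES))
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.STAGES, collapse = ", ")))
  if (identical(object@stage, "raw") && length(d) && any(d < 0))
    msg <- c(msg, "raw depths must be non-negative")
  if (length(tg) > 1L) {
    o <- order(as.integer(GenomeInfoDb::seqnames(tg)),
               GenomicRanges::start(tg))
    if (!identical(o, seq_along(tg)))
      msg <- c(msg, "targets must be sorted by (chrom, start)")
  }
  if (length(tg) && any(GenomicRanges::start(tg) < 1L))
    msg <- c(msg, "target start coordinates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ReadDepthMatrix
#'
#' @param depths numeric matrix (samples x targets) with sample IDs as
#'   rownames. Column names are set to the `"chrom:start-stop"` form of
#'   `targets`.
#' @param targets `GRanges` of capture targets (or a character vector of
#'   `"chrom:start-stop"` strings, passed to [parseTarget()]).
#' @param stage pipeline stage label; default `"raw"`.
#' @return A validated [ReadDepthMatrix-class] object.
#' @examples
#' m <- matrix(c(10, 20, 30, 12, 18, 33), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), NULL))
#' rdm <- ReadDepthMatrix(m, c("1:100-199", "1:300-399", "2:100-249"))
#' rdm
#' @export
ReadDepthMatrix <- function(depths, targets, stage = "raw") {
  if (is.character(targets))
    targets <- parseTarget(targets)
  depths <- as.matrix(depths)
  storage.mode(depths) <- "double"
  colnames(depths) <- targetStrings(targets)
  new("ReadDepthMatrix", depths = depths, targets = targets, stage = stage)
}

setMethod("show", "ReadDepthMatrix", function(object) {
  cat(sprintf("ReadDepthMatrix: %d sample(s) x %d target(s) [stage: %s]\n",
              nrow(object@depths), ncol(object@depths), object@stage))
  if (nrow(object@depths)) {
    ns <- min(3L, nrow(object@depths)); nt <- min(4L, ncol(object@depths))
    print(round(object@depths[seq_len(ns), seq_len(nt), drop = FALSE], 3))
    if (nrow(object@depths) > ns || ncol(object@depths) > nt)
      cat("...\n")
  }
})

#' @rdname ReadDepthMatrix
#' @param object,x a `ReadDepthMatrix`.
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))
#' @rdname ReadDepthMatrix
#' @export
setMethod("depths", "ReadDepthMatrix", function(object) object@depths)

#' @rdname ReadDepthMatrix
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname ReadDepthMatrix
#' @export
setMethod("sampleIds", "ReadDepthMatrix",
          function(object) rownames(object@depths))

#' @rdname ReadDepthMatrix
#' @export
setGeneric("targets", function(object) standardGeneric("targets"))
#' @rdname ReadDepthMatrix
#' @export
setMethod("targets", "ReadDepthMatrix", function(object) object@targets)

#' @rdname ReadDepthMatrix
#' @export
setGeneric("stageLabel", function(object) standardGeneric("stageLabel"))
#' @rdname ReadDepthMatrix
#' @export
setMethod("stageLabel", "ReadDepthMatrix", function(object) object@stage)

#' @rdname ReadDepthMatrix
#' @export
setMethod("dim", "ReadDepthMatrix", function(x) dim(x@depths))

## stage transitions are pipeline-ordered; helper enforces the ordering
.advanceStage <- function(object, to) {
  from <- match(object@stage, .STAGES)
  dest <- match(to, .STAGES)
  if (is.na(dest)) stop("unknown stage: ", to)
  if (dest < from)
    stop(sprintf("stage transition %s -> %s is not in pipeline order",
                 object@stage, to))
  object@stage <- to
  object
}

## subset helper keeping labels/targets in sync (internal)
.subsetRDM <- function(object, samples = NULL, targetIdx = NULL) {
  d <- object@depths; tg <- object@targets
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(targetIdx)) {
    d <- d[, targetIdx, drop = FALSE]
    tg <- tg[targetIdx]
  }
  new("ReadDepthMatrix", depths = d, targets = tg, stage = object@stage)
}

#' Alignment-record filters for coverage computation
#'
#' Defaults reproduce the coverage settings of the published exome CNV
#' protocol: fragments with mapping quality below 20 are ignored, duplicate
#' and secondary/supplementary records are excluded, base qualities are not
#' considered, and overlapping bases of a read pair are counted once per
#' fragment.
#'
#' @slot minMapQ integer phred mapping-quality threshold (records below are
#'   dropped).
#' @slot countUnit `"fragment"` (overlapping mate bases counted once) or
#'   `"read"` (each read counts independently).
#' @slot includeDuplicates logical; keep duplicate-flagged records.
#' @slot includeSecondary logical; keep secondary/supplementary records.
#' @aliases CoverageFilters-class
#' @exportClass CoverageFilters
setClass("CoverageFilters",
  representation(minMapQ = "integer", countUnit = "character",
                 includeDuplicates = "logical", includeSecondary = "logical"))

setValidity("CoverageFilters", function(object) {
  msg <- character()
  if (object@minMapQ < 0L) msg <- c(msg, "minMapQ must be >= 0")
  if (!object@countUnit %in% c("fragment", "read"))
    msg <- c(msg, "countUnit must be 'fragment' or 'read'")
  if (length(msg)) msg else TRUE
})

#' @rdname CoverageFilters-class
#' @param minMapQ,countUnit,includeDuplicates,includeSecondary see slots.
#' @return A `CoverageFilters` object.
#' @export
coverageFilters <- function(minMapQ = 20L, countUnit = c("fragment", "read"),
                            includeDuplicates = FALSE,
                            includeSecondary = FALSE) {
  new("CoverageFilters", minMapQ = as.integer(minMapQ),
      countUnit = match.arg(countUnit),
      includeDuplicates = includeDuplicates,
      includeSecondary = includeSecondary)
}

#' Target and sample filtering thresholds
#'
#' Numeric defaults are the published exome CNV protocol values: targets are
#' kept when their length is within \[10, 10000\] bp, their cohort mean depth
#' within \[10, 500\], their GC fraction within \[0.1, 0.9\] and their
#' low-complexity fraction at most 0.25; samples are kept when their mean
#' depth is within \[25, 200\] with standard deviation at most 150; after PCA
#' normalization, targets with column standard deviation above 30 are
#' removed.
#'
#' @slot minTargetLength,maxTargetLength target length bounds (bp).
#' @slot minTargetMeanRD,maxTargetMeanRD per-target cohort mean depth bounds.
#' @slot minSampleMeanRD,maxSampleMeanRD per-sample mean depth bounds.
#' @slot maxSampleSdRD per-sample depth standard-deviation bound.
#' @slot minGC,maxGC GC-fraction bounds (applied when annotation present).
#' @slot maxComplexity low-complexity-fraction bound (when annotated).
#' @slot maxTargetSdPost post-normalization per-target SD bound.
#' @aliases FilterThresholds-class
#' @exportClass FilterThresholds
setClass("FilterThresholds",
  representation(minTargetLength = "numeric", maxTargetLength = "numeric",
                 minTargetMeanRD = "numeric", maxTargetMeanRD = "numeric",
                 minSampleMeanRD = "numeric", maxSampleMeanRD = "numeric",
                 maxSampleSdRD = "numeric",
                 minGC = "numeric", maxGC = "numeric",
                 maxComplexity = "numeric", maxTargetSdPost = "numeric"))

setValidity("FilterThresholds", function(object) {
  msg <- character()
  if (object@minTargetLength > object@maxTargetLength)
    msg <- c(msg, "minTargetLength > maxTargetLength")
  if (object@minTargetMeanRD > object@maxTargetMeanRD)
    msg <- c(msg, "minTargetMeanRD > maxTargetMeanRD")
  if (object@minSampleMeanRD > object@maxSampleMeanRD)
    msg <- c(msg, "minSampleMeanRD > maxSampleMeanRD")
  if (object@minGC > object@maxGC) msg <- c(msg, "minGC > maxGC")
  vals <- c(object@minTargetLength, object@maxTargetLength,
            object@minTargetMeanRD, object@maxTargetMeanRD,
            object@minSampleMeanRD, object@maxSampleMeanRD,
            object@maxSampleSdRD, object@minGC, object@maxGC,
            object@maxComplexity, object@maxTargetSdPost)
  if (!all(is.finite(vals))) msg <- c(msg, "all thresholds must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterThresholds-class
#' @param minTargetLength,maxTargetLength,minTargetMeanRD,maxTargetMeanRD
#'   see slots.
#' @param minSampleMeanRD,maxSampleMeanRD,maxSampleSdRD see slots.
#' @param minGC,maxGC,maxComplexity,maxTargetSdPost see slots.
#' @return A `FilterThresholds` object.
#' @export
filterThresholds <- function(minTargetLength = 10, maxTargetLength = 10000,
                             minTargetMeanRD = 10, maxTargetMeanRD = 500,
                             minSampleMeanRD = 25, maxSampleMeanRD = 200,
                             maxSampleSdRD = 150,
                             minGC = 0.1, maxGC = 0.9,
                             maxComplexity = 0.25, maxTargetSdPost = 30) {
  new("FilterThresholds",
      minTargetLength = minTargetLength, maxTargetLength = maxTargetLength,
      minTargetMeanRD = minTargetMeanRD, maxTargetMeanRD = maxTargetMeanRD,
      minSampleMeanRD = minSampleMeanRD, maxSampleMeanRD = maxSampleMeanRD,
      maxSampleSdRD = maxSampleSdRD, minGC = minGC, maxGC = maxGC,
      maxComplexity = maxComplexity, maxTargetSdPost = maxTargetSdPost)
}

#' Truncated singular-value spectrum of a centred depth matrix
#'
#' Holds the top-`k` singular triples of the centred read-depth matrix.
#' Component variances are the squared singular values, non-increasing.
#' `n` is the number of candidate components of the full decomposition,
#' taken as `min(s, t)`.
#'
#' @slot variances squared singular values, length `k`, non-increasing.
#' @slot k number of computed components.
#' @slot n number of candidate components of the full decomposition.
#' @slot u left singular vectors (`s` x `k`).
#' @slot d singular values, length `k`.
#' @slot v right singular vectors (`t` x `k`).
#' @aliases SVDSpectrum-class
#' @exportClass SVDSpectrum
setClass("SVDSpectrum",
  representation(variances = "numeric", k = "integer", n = "integer",
                 u = "matrix", d = "numeric", v = "matrix"))

setValidity("SVDSpectrum", function(object) {
  msg <- character()
  v <- object@variances
  if (any(v < -1e-12)) msg <- c(msg, "variances must be non-negative")
  if (is.unsorted(rev(v), strictly = FALSE) && length(v) > 1L &&
      any(diff(v) > 1e-9 * max(v, 1)))
    msg <- c(msg, "variances must be non-increasing")
  if (object@k > object@n) msg <- c(msg, "k must be <= n")
  if (length(v) != object@k) msg <- c(msg, "length(variances) != k")
  if (length(msg)) msg else TRUE
})

#' Result of the iterative rank-selection algorithm
#'
#' `K` is the certified number of leading principal components to remove
#' during PCA normalization, equal to the count produced by the
#' full-spectrum relative-variance rule `v_i >= coefficient * sum(v) / n`.
#' `overEstimate`/`underEstimate` bracket the total variance from the
#' truncated spectrum that certified the result.
#'
#' @slot K number of components to remove.
#' @slot varianceCoefficient relative-variance coefficient (default 0.7).
#' @slot initialKFraction fraction of `n` for the first truncated SVD.
#' @slot overEstimate,underEstimate total-variance bounds at certification.
#' @slot certified TRUE when the guarantee condition held (always on return).
#' @slot kUsed number of components computed when `K` was certified.
#' @slot iterations number of truncated decompositions performed.
#' @aliases RankSelection-class
#' @exportClass RankSelection
setClass("RankSelection",
  representation(K = "integer", varianceCoefficient = "numeric",
                 initialKFraction = "numeric",
                 overEstimate = "numeric", underEstimate = "numeric",
                 certified = "logical", kUsed = "integer",
                 iterations = "integer"))

setValidity("RankSelection", function(object) {
  msg <- character()
  if (object@K < 0L) msg <- c(msg, "K must be >= 0")
  if (!anyNA(c(object@underEstimate, object@overEstimate)) &&
      object@underEstimate > object@overEstimate + 1e-9 * object@overEstimate)
    msg <- c(msg, "underEstimate must be <= overEstimate")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RankSelection", function(object) {
  cat(sprintf(
    "RankSelection: K = %d (coefficient %.2f), certified with k = %d after %d iteration(s)\n",
    object@K, object@varianceCoefficient, object@kUsed, object@iterations))
  cat(sprintf("  total-variance bounds: [%.4g, %.4g]\n",
              object@underEstimate, object@overEstimate))
})

#' Three-state copy-number HMM parameters
#'
#' The hidden states are DEL (one copy lost), DIP (diploid) and DUP (one
#' copy gained). A CNV starts at any target with probability `p` and spans
#' on average `meanTargetsPerCNV` targets (exit probability
#' `q = 1/meanTargetsPerCNV`). Transition matrices attenuate towards the
#' stationary row `(p, 1-2p, p)` with distance between consecutive targets:
#' `T(d) = f*T0 + (1-f)*Pi`, `f = exp(-d/distanceScale)`. Emissions are
#' unit-variance normals on the z-score scale with means `-M`, `0`, `+M`
#' where `M = emissionShift`. Calls with phred-scaled Q_SOME below
#' `minSomeQuality` are suppressed.
#'
#' @slot p CNV start probability per target (default 1e-8).
#' @slot meanTargetsPerCNV expected CNV length in targets (default 6).
#' @slot distanceScale attenuation scale in bp (default 70000).
#' @slot emissionShift emission mean shift in z-units (default 3).
#' @slot minSomeQuality phred threshold for reporting (default 30).
#' @slot distanceMode `"midpoint"` (midpoint-to-midpoint distance between
#'   consecutive targets) or `"gap"` (end-to-start gap).
#' @aliases HMMParameters-class
#' @exportClass HMMParameters
setClass("HMMParameters",
  representation(p = "numeric", meanTargetsPerCNV = "numeric",
                 distanceScale = "numeric", emissionShift = "numeric",
                 minSomeQuality = "integer", distanceMode = "character"))

setValidity("HMMParameters", function(object) {
  msg <- character()
  if (!(object@p > 0 && object@p < 0.5))
    msg <- c(msg, "p must be in (0, 0.5)")
  q <- 1 / object@meanTargetsPerCNV
  if (!(q > 0 && q <= 1))
    msg <- c(msg, "1/meanTargetsPerCNV must be in (0, 1]")
  if (object@distanceScale <= 0) msg <- c(msg, "distanceScale must be > 0")
  if (object@emissionShift <= 0) msg <- c(msg, "emissionShift must be > 0")
  if (object@minSomeQuality < 0L || object@minSomeQuality > 99L)
    msg <- c(msg, "minSomeQuality must be in [0, 99]")
  if (!object@distanceMode %in% c("midpoint", "gap"))
    msg <- c(msg, "distanceMode must be 'midpoint' or 'gap'")
  if (length(msg)) msg else TRUE
})

#' @rdname HMMParameters-class
#' @param p,meanTargetsPerCNV,distanceScale,emissionShift,minSomeQuality,distanceMode
#'   see slots.
#' @return An `HMMParameters` object.
#' @export
hmmParameters <- function(p = 1e-8, meanTargetsPerCNV = 6,
                          distanceScale = 70000, emissionShift = 3,
                          minSomeQuality = 30L,
                          distanceMode = c("midpoint", "gap")) {
  new("HMMParameters", p = p, meanTargetsPerCNV = meanTargetsPerCNV,
      distanceScale = distanceScale, emissionShift = emissionShift,
      minSomeQuality = as.integer(minSomeQuality),
      distanceMode = match.arg(distanceMode))
}

setMethod("show", "HMMParameters", function(object) {
  cat(sprintf(
    "HMMParameters: p = %g, mean CNV length = %g targets (q = %g)\n",
    object@p, object@meanTargetsPerCNV, 1 / object@meanTargetsPerCNV))
  cat(sprintf("  distance scale D = %g bp (%s distance), emission shift M = %g, Q_SOME threshold = %d\n",
              object@distanceScale, object@distanceMode,
              object@emissionShift, object@minSomeQuality))
})

## state order used throughout: DEL = 1, DIP = 2, DUP = 3
.STATES <- c("DEL", "DIP", "DUP")
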