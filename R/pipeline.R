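#' Run the full discovery pipeline from a read-depth matrix
#'
#' Normalization ([normalizeDepths()]) followed by HMM discovery
#' ([discoverCNVs()]), writing the z-score matrix, the exclusion reports
#' and the `.xcnv` call table under `outPrefix`. Every per-sample step is
#' independent, so results do not depend on sample order.
#'
#' @param rdm raw [ReadDepthMatrix-class] (or a matrix file path).
#' @param outPrefix output path prefix; files written are
#'   `<prefix>.zscores.txt`, `<prefix>.xcnv` and
#'   `<prefix>.excluded_{targets,samples,targets_post}.txt`.
#' @param thresholds a [FilterThresholds-class].
#' @param params an [HMMParameters-class].
#' @param varianceCoefficient,initialKFraction,K passed to
#'   [normalizeDepths()].
#' @param verbose log progress (chosen K, filter counts) to stderr.
#' @return list with `calls`, `normalization` and output `paths`,
#'   invisibly.
#' @export
runPipeline <- function(rdm, outPrefix, thresholds = filterThresholds(),
                        params = hmmParameters(),
                        varianceCoefficient = 0.7, initialKFraction = 0.1,
                        K = NULL, verbose = TRUE) {
  if (is.character(rdm)) rdm <- readDepthMatrix(rdm)
  log <- function(...) if (verbose) message(sprintf(...))
  norm <- normalizeDepths(rdm, thresholds, varianceCoefficient,
                          initialKFraction, K = K)
  log("excluded %d target(s) pre, %d sample(s), %d target(s) post",
      nrow(norm$reports$targets_pre), nrow(norm$reports$samples),
      nrow(norm$reports$targets_post))
  log("removing K = %d component(s) [k = %d, %d iteration(s)]",
      norm$selection@K, norm$selection@kUsed, norm$selection@iterations)
  calls <- discoverCNVs(norm$z, norm$original, params)
  log("%d CNV call(s) at Q_SOME >= %d", nrow(calls), params@minSomeQuality)
  paths <- c(z = paste0(outPrefix, ".zscores.txt"),
             xcnv = paste0(outPrefix, ".xcnv"),
             targets_pre = paste0(outPrefix, ".excluded_targets.txt"),
             samples = paste0(outPrefix, ".excluded_samples.txt"),
             targets_post = paste0(outPrefix, ".excluded_targets_post.txt"))
  writeDepthMatrix(norm$z, paths[["z"]])
  writeXcnv(calls, paths[["xcnv"]])
  for (nm in c("targets_pre", "samples", "targets_post"))
    utils::write.table(norm$reports[[nm]], paths[[nm]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(list(calls = calls, normalization = norm, paths = paths))
}

## ---- command-line interface -------------------------------------------
## Thin layer over the package functions. Exit codes: 0 success, 1 data
## error, 2 usage error.

.cliUsage <- function() {
  paste(
    "usage: wescnv <command> [options]",
    "",
    "commands:",
    "  coverage   per-target mean depth from SAM/BAM files",
    "             --targets FILE --out FILE [--min-mapq N] [--count-unit fragment|read]",
    "             [--include-duplicates] [--include-secondary] [--annotations FILE] FILE...",
    "  normalize  filter, centre, PCA-normalize and z-score a matrix",
    "             --matrix FILE --out FILE [--orig-out FILE] [--annotations FILE]",
    "             [--variance-coefficient X] [--initial-k-fraction X] [--K N]",
    "  discover   call CNVs from a z-score matrix, write .xcnv",
    "             --zscores FILE --out FILE [--orig FILE] [--min-some-quality N]",
    "             [--p X] [--mean-targets-per-cnv N] [--distance-scale BP]",
    "             [--emission-shift X]",
    "  pipeline   normalize + discover from a raw matrix",
    "             --matrix FILE --out-prefix PREFIX [--config YAML] [--seed N]",
    "             [normalize/discover options]",
    "  simulate   generate a synthetic cohort with embedded CNVs",
    "             --samples N --targets N --out-prefix PREFIX [--seed N]",
    "             [--batch-rank N] [--batch-strength X] [--cnvs TSV]",
    "  match      concordance report between two .xcnv files",
    "             --a FILE --b FILE",
    sep = "\n")
}

## parse "--key value" / "--flag" argument lists against a prototype of
## defaults; logical defaults make flags, everything else takes a value
.cliParse <- function(args, proto) {
  out <- proto
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (!key %in% names(proto))
        stop("unknown option: ", a, call. = FALSE)
      if (is.logical(proto[[key]])) {
        out[[key]] <- TRUE
      } else {
        if (i == length(args)) stop("missing value for ", a, call. = FALSE)
        i <- i + 1L
        val <- args[[i]]
        out[[key]] <- if (is.numeric(proto[[key]])) {
          v <- suppressWarnings(as.numeric(val))
          if (is.na(v)) stop("non-numeric value for ", a, call. = FALSE)
          v
        } else val
      }
    } else {
      positional <- c(positional, a)
    }
    i <- i + 1L
  }
  out$positional <- positional
  out
}

.cliThresholds <- function(o) {
  filterThresholds(
    minTargetLength = o$min_target_length,
    maxTargetLength = o$max_target_length,
    minTargetMeanRD = o$min_target_mean_rd,
    maxTargetMeanRD = o$max_target_mean_rd,
    minSampleMeanRD = o$min_sample_mean_rd,
    maxSampleMeanRD = o$max_sample_mean_rd,
    maxSampleSdRD = o$max_sample_sd_rd,
    minGC = o$min_gc, maxGC = o$max_gc,
    maxComplexity = o$max_complexity,
    maxTargetSdPost = o$max_target_sd_post)
}

.cliHmm <- function(o) {
  if (o$min_some_quality < 0 || o$min_some_quality > 99)
    stop("usage: --min-some-quality must be in [0, 99]", call. = FALSE)
  hmmParameters(p = o$p, meanTargetsPerCNV = o$mean_targets_per_cnv,
                distanceScale = o$distance_scale,
                emissionShift = o$emission_shift,
                minSomeQuality = o$min_some_quality,
                distanceMode = o$distance_mode)
}

.cliThresholdProto <- function() {
  list(min_target_length = 10, max_target_length = 10000,
       min_target_mean_rd = 10, max_target_mean_rd = 500,
       min_sample_mean_rd = 25, max_sample_mean_rd = 200,
       max_sample_sd_rd = 150, min_gc = 0.1, max_gc = 0.9,
       max_complexity = 0.25, max_target_sd_post = 30)
}

.cliHmmProto <- function() {
  list(p = 1e-8, mean_targets_per_cnv = 6, distance_scale = 70000,
       emission_shift = 3, min_some_quality = 30,
       distance_mode = "midpoint")
}

#' Command-line entry point
#'
#' Dispatches the subcommands documented by `wescnvMain("--help")`; the
#' `exec/wescnv` script forwards `commandArgs(TRUE)` here. Identical inputs,
#' flags and seed produce byte-identical outputs.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly (0 success, 1 data error, 2 usage
#'   error).
#' @export
wescnvMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[[1L]] %in% c("--help", "-h", "help")) {
    cat(.cliUsage(), "\n")
    return(invisible(0L))
  }
  cmd <- args[[1L]]
  rest <- args[-1L]
  known <- c("coverage", "normalize", "discover", "pipeline", "simulate",
             "match")
  if (!cmd %in% known) {
    message("wescnv: unknown command '", cmd, "'\n", .cliUsage())
    return(invisible(2L))
  }
  status <- tryCatch({
    switch(cmd,
      coverage = .cmdCoverage(rest),
      normalize = .cmdNormalize(rest),
      discover = .cmdDiscover(rest),
      pipeline = .cmdPipeline(rest),
      simulate = .cmdSimulate(rest),
      match = .cmdMatch(rest))
    0L
  }, error = function(e) {
    message("wescnv ", cmd, ": ", conditionMessage(e))
    if (grepl("^usage:|^unknown option|^missing value|^non-numeric value",
              conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}

.cmdCoverage <- function(args) {
  o <- .cliParse(args, c(list(
    targets = "", out = "", annotations = "", min_mapq = 20,
    count_unit = "fragment", include_duplicates = FALSE,
    include_secondary = FALSE)))
  if (!nzchar(o$targets) || !nzchar(o$out) || !length(o$positional))
    stop("usage: coverage --targets FILE --out FILE FILE...", call. = FALSE)
  tg <- readTargets(o$targets)
  if (nzchar(o$annotations)) {
    ## protocol: annotation-excluded targets are removed before the matrix
    tg <- annotateTargets(tg, table = o$annotations)
    th <- filterThresholds()
    mc <- GenomicRanges::mcols(tg)
    keep <- mc$gc >= th@minGC & mc$gc <= th@maxGC &
      mc$complexity <= th@maxComplexity
    tg <- tg[keep]
  }
  f <- coverageFilters(minMapQ = o$min_mapq, countUnit = o$count_unit,
                       includeDuplicates = o$include_duplicates,
                       includeSecondary = o$include_secondary)
  writeDepthMatrix(coverageMatrix(o$positional, tg, f), o$out)
}

.cmdNormalize <- function(args) {
  o <- .cliParse(args, c(list(
    matrix = "", out = "", orig_out = "", annotations = "",
    variance_coefficient = 0.7, initial_k_fraction = 0.1, K = -1),
    .cliThresholdProto()))
  if (!nzchar(o$matrix) || !nzchar(o$out))
    stop("usage: normalize --matrix FILE --out FILE", call. = FALSE)
  rdm <- readDepthMatrix(o$matrix)
  if (nzchar(o$annotations))
    rdm@targets <- annotateTargets(targets(rdm), table = o$annotations)
  norm <- normalizeDepths(rdm, .cliThresholds(o),
                          varianceCoefficient = o$variance_coefficient,
                          initialKFraction = o$initial_k_fraction,
                          K = if (o$K >= 0) as.integer(o$K) else NULL)
  message(sprintf("K = %d (k = %d, %d iteration(s))", norm$selection@K,
                  norm$selection@kUsed, norm$selection@iterations))
  writeDepthMatrix(norm$z, o$out)
  if (nzchar(o$orig_out)) writeDepthMatrix(norm$original, o$orig_out)
}

.cmdDiscover <- function(args) {
  o <- .cliParse(args, c(list(zscores = "", orig = "", out = ""),
                         .cliHmmProto()))
  if (!nzchar(o$zscores) || !nzchar(o$out))
    stop("usage: discover --zscores FILE --out FILE", call. = FALSE)
  z <- readDepthMatrix(o$zscores, stage = "zscored")
  orig <- if (nzchar(o$orig)) readDepthMatrix(o$orig) else NULL
  writeXcnv(discoverCNVs(z, orig, .cliHmm(o)), o$out)
}

.cmdPipeline <- function(args) {
  o <- .cliParse(args, c(list(
    matrix = "", out_prefix = "", config = "", seed = 0,
    variance_coefficient = 0.7, initial_k_fraction = 0.1, K = -1),
    .cliThresholdProto(), .cliHmmProto()))
  if (nzchar(o$config)) {
    cfg <- yaml::read_yaml(o$config)
    bad <- setdiff(names(cfg), names(o))
    if (length(bad))
      stop("unknown option: config key '", bad[1L], "'", call. = FALSE)
    for (nm in names(cfg)) o[[nm]] <- cfg[[nm]]
  }
  if (!nzchar(o$matrix) || !nzchar(o$out_prefix))
    stop("usage: pipeline --matrix FILE --out-prefix PREFIX", call. = FALSE)
  set.seed(as.integer(o$seed))
  runPipeline(readDepthMatrix(o$matrix), o$out_prefix,
              thresholds = .cliThresholds(o), params = .cliHmm(o),
              varianceCoefficient = o$variance_coefficient,
              initialKFraction = o$initial_k_fraction,
              K = if (o$K >= 0) as.integer(o$K) else NULL)
}

.cmdSimulate <- function(args) {
  o <- .cliParse(args, list(
    samples = 0, targets = 0, out_prefix = "", seed = 1,
    batch_rank = 0, batch_strength = 0.15, noise = "poisson",
    cnvs = ""))
  if (o$samples < 1 || o$targets < 1 || !nzchar(o$out_prefix))
    stop("usage: simulate --samples N --targets N --out-prefix PREFIX",
         call. = FALSE)
  specs <- if (nzchar(o$cnvs))
    utils::read.table(o$cnvs, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  sim <- simulateCohort(simulationConfig(
    nSamples = o$samples, nTargets = o$targets, batchRank = o$batch_rank,
    batchStrength = o$batch_strength, noiseModel = o$noise,
    cnvSpecs = specs, seed = o$seed))
  writeDepthMatrix(sim$matrix, paste0(o$out_prefix, ".matrix.txt"))
  tg <- targets(sim$matrix)
  utils::write.table(
    data.frame(target = targetStrings(tg),
               gc = GenomicRanges::mcols(tg)$gc,
               complexity = GenomicRanges::mcols(tg)$complexity),
    paste0(o$out_prefix, ".annotations.txt"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paste0(o$out_prefix, ".truth.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

.cmdMatch <- function(args) {
  o <- .cliParse(args, list(a = "", b = ""))
  if (!nzchar(o$a) || !nzchar(o$b))
    stop("usage: match --a FILE --b FILE", call. = FALSE)
  rep <- matchCalls(readXcnv(o$a), readXcnv(o$b))
  cat(sprintf("calls_a\t%d\ncalls_b\t%d\nexact\t%d\noverlap\t%d\nunmatched\t%d\n",
              rep$nA, rep$nB, rep$exact, rep$overlap, rep$unmatched))
  if (nrow(rep$pairs))
    cat(sprintf("overlap_diff_1_target\t%d\n",
                sum(rep$pairs$match == "overlap" & rep$pairs$targetDiff <= 1)))
}
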