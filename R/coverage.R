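#' @importFrom GenomicAlignments readGAlignments grglist
#' @importFrom Rsamtools ScanBamParam scanBamFlag scanBamHeader asBam
NULL

## convert a SAM text file to a temporary BAM (+ index) for reading
.ensureBam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  } else {
    path
  }
}

.checkSorted <- function(bam) {
  hd <- Rsamtools::scanBamHeader(bam)[[1L]]$text
  so <- hd[names(hd) == "@HD"]
  if (length(so)) {
    tags <- unlist(so)
    soTag <- grep("^SO:", tags, value = TRUE)
    if (length(soTag) && !any(soTag == "SO:coordinate"))
      stop("alignments are not coordinate-sorted (", soTag[1L], ")")
  }
  invisible(TRUE)
}

.bamSampleName <- function(bam, fallback) {
  hd <- Rsamtools::scanBamHeader(bam)[[1L]]$text
  rg <- hd[names(hd) == "@RG"]
  if (length(rg)) {
    sm <- grep("^SM:", unlist(rg), value = TRUE)
    if (length(sm)) return(sub("^SM:", "", sm[1L]))
  }
  sub("\\.(bam|sam)$", "", basename(fallback), ignore.case = TRUE)
}

## aligned reference blocks of every passing record, optionally collapsed to
## one contribution per fragment (per-base depth counted once per QNAME)
.alignedBlocks <- function(bam, filters) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (filters@includeDuplicates) NA else FALSE,
    isSecondaryAlignment = if (filters@includeSecondary) NA else FALSE,
    isSupplementaryAlignment = if (filters@includeSecondary) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "qname",
                                   mapqFilter = filters@minMapQ)
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  ## D/N gaps in the CIGAR consume reference but are not counted as covered
  grl <- GenomicAlignments::grglist(ga, drop.D.ranges = TRUE)
  gr <- unlist(grl, use.names = FALSE)
  GenomicRanges::strand(gr) <- "*"   # depth is strand-blind
  if (length(gr) && filters@countUnit == "fragment") {
    qn <- rep(S4Vectors::mcols(ga)$qname, S4Vectors::elementNROWS(grl))
    gr <- unlist(GenomicRanges::reduce(GenomicRanges::split(gr, qn)),
                 use.names = FALSE)
  }
  gr
}

#' Per-target mean read depth for one sample
#'
#' For each target, the value is the sum over target bases of the per-base
#' depth contributed by passing alignments, divided by the target length.
#' Aligned bases are the CIGAR reference-consuming, sequence-matched
#' positions (`M`/`=`/`X`); deletions within a read (`D`) and skips (`N`)
#' consume reference but do not count as covered. With
#' `countUnit = "fragment"` a base overlapped by both mates of a pair counts
#' once; with `"read"` every read counts. Base qualities are ignored.
#'
#' @param path a coordinate-sorted SAM or BAM file (SAM is converted to a
#'   temporary BAM internally).
#' @param targets `GRanges` of capture targets.
#' @param filters a [CoverageFilters-class]; see [coverageFilters()].
#' @param sampleName optional sample name; default is the `SM` tag of the
#'   first read group, falling back to the file base name.
#' @return named numeric vector of mean depths, one per target, named by the
#'   sample.
#' @export
targetCoverage <- function(path, targets, filters = coverageFilters(),
                           sampleName = NULL) {
  bam <- .ensureBam(path)
  .checkSorted(bam)
  if (is.null(sampleName)) sampleName <- .bamSampleName(bam, path)
  hd <- Rsamtools::scanBamHeader(bam)[[1L]]
  bamChroms <- names(hd$targets)
  chromT <- unique(as.character(GenomeInfoDb::seqnames(targets)))
  absent <- setdiff(chromT, bamChroms)
  if (length(absent))
    warning("target chromosome(s) absent from alignment header: ",
            paste(absent, collapse = ", "), " (coverage 0)")
  gr <- .alignedBlocks(bam, filters)
  cov <- numeric(length(targets))
  if (length(gr)) {
    lv <- union(GenomeInfoDb::seqlevels(targets), GenomeInfoDb::seqlevels(gr))
    tg2 <- targets; GenomeInfoDb::seqlevels(tg2) <- lv
    GenomeInfoDb::seqlevels(gr) <- lv
    hits <- GenomicRanges::findOverlaps(tg2, gr, ignore.strand = TRUE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ovw <- pmin(GenomicRanges::end(tg2)[qh], GenomicRanges::end(gr)[sh]) -
        pmax(GenomicRanges::start(tg2)[qh], GenomicRanges::start(gr)[sh]) + 1L
      sums <- tapply(ovw, qh, sum)
      cov[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  cov <- cov / GenomicRanges::width(targets)
  names(cov) <- rep(sampleName, length(cov))
  structure(cov, sample = sampleName)
}

#' Coverage matrix for a cohort of alignment files
#'
#' One matrix row per input file, in input order; rows are computed
#' independently, so permuting the input files permutes the rows and nothing
#' else. Any per-file failure aborts with the file named.
#'
#' @param paths character vector of SAM/BAM files.
#' @param targets shared `GRanges` target list.
#' @param filters a [CoverageFilters-class].
#' @param sampleNames optional per-file sample names.
#' @return A [ReadDepthMatrix-class] at stage `"raw"`.
#' @export
coverageMatrix <- function(paths, targets, filters = coverageFilters(),
                           sampleNames = NULL) {
  rows <- vector("list", length(paths))
  ids <- character(length(paths))
  for (i in seq_along(paths)) {
    res <- tryCatch(
      targetCoverage(paths[[i]], targets, filters,
                     sampleName = sampleNames[i]),
      error = function(e)
        stop("coverage failed for ", paths[[i]], ": ", conditionMessage(e),
             call. = FALSE))
    rows[[i]] <- as.numeric(res)
    ids[i] <- attr(res, "sample")
  }
  vals <- do.call(rbind, rows)
  rownames(vals) <- ids
  ReadDepthMatrix(vals, targets)
}
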