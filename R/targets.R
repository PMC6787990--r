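#' Parse "chrom:start-stop" target strings
#'
#' Targets use 1-based inclusive coordinates throughout the package, matching
#' the `chrom:start-stop` headers of the tab-delimited read-depth matrix
#' format. Parsing and formatting ([targetStrings()]) are mutual inverses on
#' all valid intervals.
#'
#' @param text character vector of `"chrom:start-stop"` strings.
#' @return A `GRanges` with one range per input string.
#' @examples
#' parseTarget(c("1:100-199", "X:5-5"))
#' @export
parseTarget <- function(text) {
  m <- regmatches(text, regexec("^(.+):([0-9]+)-([0-9]+)$", text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed target string: '", text[which(bad)[1L]],
         "' (expected chrom:start-stop)")
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.numeric(vapply(m, `[`, "", 3L))
  stop_ <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(start < 1))
    stop("target start must be >= 1 in '", text[which(start < 1)[1L]], "'")
  if (any(stop_ < start)) {
    i <- which(stop_ < start)[1L]
    stop("target stop < start in '", text[i], "'")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, stop_))
}

#' @rdname parseTarget
#' @param targets a `GRanges`.
#' @export
targetStrings <- function(targets) {
  sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(targets)),
          GenomicRanges::start(targets), GenomicRanges::end(targets))
}

#' Read a target list from BED or plain interval text
#'
#' BED files (detected by a `.bed` extension or by tab-separated 3+ column
#' content) use 0-based half-open coordinates and are converted to the
#' package's 1-based inclusive convention at this boundary (a BED line
#' `chr1 99 199` becomes `chr1:100-199`). Plain files contain one
#' `chrom:start-stop` string per line, already 1-based inclusive.
#'
#' @param path file path.
#' @return A `GRanges`, sorted by (chromosome, start).
#' @export
readTargets <- function(path) {
  if (!file.exists(path)) stop("target file not found: ", path)
  isBed <- grepl("\\.bed$", path, ignore.case = TRUE)
  if (!isBed) {
    first <- readLines(path, n = 1L)
    isBed <- grepl("\t", first)
  }
  gr <- if (isBed) {
    GenomicRanges::granges(rtracklayer::import(path, format = "bed"))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parseTarget(trimws(lines))
  }
  GenomeInfoDb::sortSeqlevels(gr)
  gr[order(as.integer(GenomeInfoDb::seqnames(gr)), GenomicRanges::start(gr))]
}

#' Distances between consecutive targets
#'
#' Returns a vector of length `length(targets) - 1` with the distance (bp)
#' between each target and the next one. With `mode = "midpoint"` (the
#' default used by the HMM transitions) the distance is between target
#' midpoints, floored at 0; with `mode = "gap"` it is the number of bases
#' strictly between the two targets. Consecutive targets on different
#' chromosomes get `Inf`, which decouples the HMM across the break.
#'
#' @param targets sorted `GRanges`.
#' @param mode `"midpoint"` or `"gap"`.
#' @return numeric vector (may contain `Inf`).
#' @export
targetDistances <- function(targets, mode = c("midpoint", "gap")) {
  mode <- match.arg(mode)
  n <- length(targets)
  if (n < 2L) return(numeric(0))
  chrom <- as.character(GenomeInfoDb::seqnames(targets))
  s <- GenomicRanges::start(targets); e <- GenomicRanges::end(targets)
  d <- if (mode == "midpoint") {
    mid <- (s + e) / 2
    pmax(mid[-1L] - mid[-n], 0)
  } else {
    pmax(s[-1L] - e[-n] - 1, 0)
  }
  d[chrom[-1L] != chrom[-n]] <- Inf
  d
}

#' Annotate targets with GC and low-complexity fractions
#'
#' Either from a reference FASTA (GC fraction over the target span; the
#' complexity fraction is the fraction of soft-masked, i.e. lowercase,
#' reference bases) or from a pre-computed annotation table with columns
#' `target`, `gc`, `complexity` (`target` in `"chrom:start-stop"` form).
#'
#' @param targets `GRanges`.
#' @param fasta optional reference FASTA path. Masked-case is honoured, so
#'   the file is read verbatim rather than through an upper-casing reader.
#' @param table optional annotation table path (TSV with header).
#' @return `targets` with `gc` and `complexity` metadata columns.
#' @export
annotateTargets <- function(targets, fasta = NULL, table = NULL) {
  if (!is.null(table)) {
    tab <- utils::read.table(table, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("target", "gc", "complexity")
    if (!all(need %in% names(tab)))
      stop("annotation table must have columns: ",
           paste(need, collapse = ", "))
    idx <- match(targetStrings(targets), tab$target)
    if (anyNA(idx))
      stop("annotation table missing target: ",
           targetStrings(targets)[which(is.na(idx))[1L]])
    GenomicRanges::mcols(targets)$gc <- tab$gc[idx]
    GenomicRanges::mcols(targets)$complexity <- tab$complexity[idx]
    return(targets)
  }
  if (is.null(fasta)) stop("provide either a FASTA or an annotation table")
  seqs <- Biostrings::readBStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chrom <- as.character(GenomeInfoDb::seqnames(targets))
  if (!all(chrom %in% names(seqs)))
    stop("chromosome absent from FASTA: ",
         setdiff(chrom, names(seqs))[1L])
  gc <- numeric(length(targets)); cplx <- numeric(length(targets))
  for (i in seq_along(targets)) {
    sq <- as.character(Biostrings::subseq(
      seqs[[chrom[i]]], GenomicRanges::start(targets)[i],
      GenomicRanges::end(targets)[i]))
    bases <- strsplit(sq, "")[[1L]]
    cplx[i] <- mean(bases %in% c("a", "c", "g", "t", "n"))
    gc[i] <- mean(toupper(bases) %in% c("G", "C"))
  }
  GenomicRanges::mcols(targets)$gc <- gc
  GenomicRanges::mcols(targets)$complexity <- cplx
  targets
}
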