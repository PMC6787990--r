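#' Read a tab-delimited read-depth matrix
#'
#' The dialect is the one used by the exome CNV tools this package
#' interoperates with: a header row of `chrom:start-stop` target strings
#' (optionally preceded by a corner token such as `Matrix`), then one row per
#' sample whose first column is the sample identifier. Matrices are dense;
#' any cell that cannot be parsed as a number is an error (reported with its
#' line number), never a missing value.
#'
#' @param path file path.
#' @param stage stage label to attach; default `"raw"`.
#' @return A [ReadDepthMatrix-class].
#' @seealso [writeDepthMatrix()]
#' @export
readDepthMatrix <- function(path, stage = "raw") {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty matrix file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ## header may or may not carry a corner cell over the sample-ID column
  hasCorner <- if (length(body)) length(header) == length(body[[1L]])
               else !grepl("^.+:[0-9]+-[0-9]+$", header[[1L]])
  targetNames <- if (hasCorner) header[-1L] else header
  if (length(body)) {
    widths <- vapply(body, length, 1L)
    if (any(widths != length(targetNames) + 1L))
      stop("ragged row at line ", which(widths != length(targetNames) + 1L)[1L] + 1L,
           " of ", path)
  }
  tg <- parseTarget(targetNames)
  ids <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sample '", ids[duplicated(ids)][1L],
         "' at line ", which(duplicated(ids))[1L] + 1L, " of ", path)
  vals <- matrix(0, nrow = length(body), ncol = length(tg),
                 dimnames = list(ids, targetNames))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v))
      stop("non-numeric cell '", body[[i]][-1L][which(is.na(v))[1L]],
           "' at line ", i + 1L, " of ", path)
    vals[i, ] <- v
  }
  ReadDepthMatrix(vals, tg, stage = stage)
}

#' Write a read-depth matrix
#'
#' Tab-delimited with a `Matrix` corner cell, target-string header and
#' leading sample-ID column, so the output can be consumed by the same
#' ecosystem of tools that produce this dialect. Values are formatted with
#' `sprintf("%.*f")`, i.e. C printf rounding of the binary double (half-even
#' on representable ties).
#'
#' @param object a [ReadDepthMatrix-class].
#' @param path output path.
#' @param precision decimal places (default 2).
#' @return `path`, invisibly.
#' @export
writeDepthMatrix <- function(object, path, precision = 2L) {
  d <- depths(object)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Matrix", targetStrings(targets(object))),
                   collapse = "\t"), con)
  fmt <- paste0("%.", precision, "f")
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i], sprintf(fmt, d[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Merge per-sample GATK interval-summary tables into a matrix
#'
#' Each input file is one sample's DepthOfCoverage `sample_interval_summary`
#' table: a `Target` column of `chrom:start-stop` strings plus a
#' mean-coverage column whose header ends in `_mean_cvg` (override with
#' `meanColumn` for other dialects). Comma- and tab-separated files are both
#' accepted. All files must list the identical targets in identical order;
#' divergence is an error, never a silent reorder.
#'
#' @param paths character vector of per-sample files; output rows keep this
#'   order.
#' @param meanColumn optional exact mean-coverage column name.
#' @param sampleNames optional sample names; default is the `_mean_cvg`
#'   header prefix, falling back to the file base name.
#' @return A [ReadDepthMatrix-class] with one row per input file.
#' @export
mergeGatkDepths <- function(paths, meanColumn = NULL, sampleNames = NULL) {
  if (!length(paths)) stop("no input files")
  rows <- vector("list", length(paths))
  ids <- character(length(paths))
  refTargets <- NULL
  for (i in seq_along(paths)) {
    first <- readLines(paths[[i]], n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- utils::read.table(paths[[i]], header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!"Target" %in% names(tab))
      stop("no 'Target' column in ", paths[[i]])
    col <- meanColumn
    if (is.null(col)) {
      hit <- grep("_mean_cvg$", names(tab), value = TRUE)
      if (length(hit) != 1L)
        stop("expected exactly one '*_mean_cvg' column in ", paths[[i]],
             "; found ", length(hit), " (use meanColumn= to select)")
      col <- hit
    } else if (!col %in% names(tab)) {
      stop("column '", col, "' not found in ", paths[[i]])
    }
    if (is.null(refTargets)) {
      refTargets <- tab$Target
    } else if (!identical(tab$Target, refTargets)) {
      j <- which(tab$Target != refTargets | is.na(tab$Target))[1L]
      if (is.na(j)) j <- min(length(tab$Target), length(refTargets)) + 1L
      stop("target list in ", paths[[i]], " diverges from ", paths[[1L]],
           " at entry ", j, " ('", tab$Target[j], "' vs '", refTargets[j], "')")
    }
    ids[i] <- if (!is.null(sampleNames)) sampleNames[i]
              else if (grepl("_mean_cvg$", col)) sub("_mean_cvg$", "", col)
              else tools::file_path_sans_ext(basename(paths[[i]]))
    rows[[i]] <- as.numeric(tab[[col]])
  }
  vals <- do.call(rbind, rows)
  rownames(vals) <- ids
  ReadDepthMatrix(vals, parseTarget(refTargets))
}
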