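# Readers and writers for the plain-text formats the pipeline touches:
# BED3/BED6 intervals, bedGraph coverage, TSV matrices with a feature-id
# first column, and the sample metadata table. All interval I/O is 0-based
# half-open; strand is ignored throughout (H3K27Ac signal is unstranded).

#' Read a BED file of genomic intervals
#'
#' Accepts BED3 or wider; optional columns 4 and 5 are returned as `name`
#' and `score`. Input order is preserved and every interval is validated
#' (`start < end`). Malformed lines raise an error naming the line number.
#'
#' @param path BED file (tab-separated, no header; `track`/`browser`/`#`
#'   lines are skipped).
#' @return data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop(sprintf("%s: malformed BED line %d (fewer than 3 fields)",
                 path, lineno[bad]), call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("%s: malformed BED line %d (non-numeric coordinate)",
                 path, lineno[bad]), call. = FALSE)
  }
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  bad <- which(out$start >= out$end)
  if (length(bad)) {
    stop(sprintf("%s: zero- or negative-length interval at line %d",
                 path, lineno[bad[1]]), call. = FALSE)
  }
  out
}

#' Write intervals as BED
#'
#' @param x interval data frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x, "BED output")
  cols <- c("chrom", "start", "end")
  if (!is.null(x$name)) cols <- c(cols, "name")
  if (!is.null(x$score) && !is.null(x$name)) cols <- c(cols, "score")
  fmt <- x[, cols, drop = FALSE]
  fmt$start <- format(fmt$start, scientific = FALSE, trim = TRUE)
  fmt$end <- format(fmt$end, scientific = FALSE, trim = TRUE)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, value; `track` lines
#'   skipped). Values may be fractional (normalized tracks).
#' @return data frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    bad <- which(lengths(fields) < 4)[1]
    stop(sprintf("%s: malformed bedGraph line %d", path, lineno[bad]),
         call. = FALSE)
  }
  out <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end) || anyNA(out$value)) {
    stop(path, ": non-numeric field in bedGraph", call. = FALSE)
  }
  out
}

#' Sum base-level coverage over intervals
#'
#' For each query interval returns the sum over covered bases of the
#' per-base coverage value, i.e. `sum(value * overlap_width)` across
#' bedGraph segments. Intervals on chromosomes absent from the coverage
#' track get a count of 0 with a warning.
#'
#' @param coverage data frame as returned by [read_bedgraph()].
#' @param intervals query interval data frame.
#' @return numeric vector of per-interval counts (possibly fractional).
#' @export
interval_coverage <- function(coverage, intervals) {
  intervals <- validate_intervals(intervals, "query intervals")
  counts <- numeric(nrow(intervals))
  if (!nrow(coverage) || !nrow(intervals)) {
    if (nrow(intervals)) {
      warning("coverage track is empty; all counts are 0", call. = FALSE)
    }
    return(counts)
  }
  missing_chrom <- !(intervals$chrom %in% unique(coverage$chrom))
  if (any(missing_chrom)) {
    warning("interval chromosome(s) absent from coverage: ",
            paste(unique(intervals$chrom[missing_chrom]), collapse = ", "),
            "; their counts are 0", call. = FALSE)
  }
  cov_gr <- intervals_to_gr(coverage)
  q_gr <- intervals_to_gr(intervals)
  hits <- GenomicRanges::findOverlaps(q_gr, cov_gr)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(q_gr)[qh], IRanges::ranges(cov_gr)[sh]))
    contrib <- ov * coverage$value[sh]
    agg <- rowsum(contrib, group = qh)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  counts
}

#' Read / write a numeric feature-by-sample matrix as TSV
#'
#' First column holds feature ids; remaining columns are samples.
#'
#' @param path TSV file with a header row.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(path, ": expected feature id column plus samples",
                         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with rownames.
#' @param id_col header for the feature id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SAMPLE_CATEGORIES <- c("tumor_cell_line", "primary_tumor", "normal")

#' Read and validate the sample metadata table
#'
#' Expects columns `sample_id`, `category` (one of tumor_cell_line /
#' primary_tumor / normal), `subtype`, `chip_library_size`,
#' `input_library_size` (both > 0).
#'
#' @param path TSV with header.
#' @return validated data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

validate_sample_metadata <- function(md) {
  need <- c("sample_id", "category", "subtype",
            "chip_library_size", "input_library_size")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(md$category), SAMPLE_CATEGORIES)
  if (length(bad)) {
    stop("unknown sample category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  if (any(md$chip_library_size <= 0) || any(md$input_library_size <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  md
}
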