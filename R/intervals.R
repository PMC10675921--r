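# Genomic interval engine.
#
# All coordinates throughout the package are 0-based half-open (BED
# convention): an interval covers bases start .. end-1 and a point position p
# is the interval [p, p+1). Strand is one of "+", "-", "*" (unstranded).
# Intervals are carried as plain data.frames with columns chrom, start, end,
# strand; GenomicRanges/IRanges provide the overlap machinery internally
# (with the +1 shift to their 1-based closed convention).

#' Construct a validated interval table
#'
#' @param chrom character vector of contig names.
#' @param start,end integer-like vectors, 0-based half-open.
#' @param strand strand vector, recycled; one of `"+"`, `"-"`, `"*"`.
#' @param ... additional columns (e.g. `name`, `score`), recycled.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand` and any
#'   extra columns.
#' @examples
#' gintervals("chr1", 10, 20, "+")
#' @export
gintervals <- function(chrom, start, end, strand = "*", ...) {
  if (length(chrom) == 0) {
    x <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), strand = character(),
                    stringsAsFactors = FALSE)
    for (nm in names(list(...))) x[[nm]] <- list(...)[[nm]][0]
    return(x)
  }
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) x[[nm]] <- extra[[nm]]
  validate_intervals(x)
  x
}

# Invariant checks shared by every interval consumer.
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (is.null(x$strand)) x$strand <- "*"
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stopf("interval with empty contig name")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stopf("invalid interval (need 0 <= start < end) at row %d: %s:%s-%s",
          bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]])
  if (any(!x$strand %in% c("+", "-", "*")))
    stopf("strand must be one of '+', '-', '*'")
  invisible(x)
}

# data.frame (0-based half-open) -> GRanges (1-based closed).
as_granges <- function(x) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  strand <- if (is.null(x$strand)) "*" else x$strand
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1, x$end),
                         strand = strand)
}

from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a BED3/BED6 file
#'
#' Coordinates are kept in the file's native 0-based half-open convention.
#' Lines with `start >= end` are rejected with an error naming the line.
#'
#' @param path path to a BED file.
#' @param stranded if `TRUE`, take strand from column 6; otherwise all
#'   intervals are unstranded.
#' @return interval data.frame with `name` and `score` columns when present.
#' @export
read_bed <- function(path, stranded = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(gintervals(character(), numeric(), numeric())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("BED line %d has fewer than 3 fields", which(nf < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stopf("non-numeric BED coordinate on line %d",
          which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  if (length(bad))
    stopf("BED line %d: start >= end (%s:%s-%s)",
          bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]])
  x <- data.frame(chrom = chrom, start = start, end = end,
                  strand = "*", stringsAsFactors = FALSE)
  if (any(nf >= 4)) x$name <- ifelse(nf >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else ".", ""), ".")
  if (any(nf >= 5)) x$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "0", "")))
  if (stranded) {
    s <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "*", "")
    s[!s %in% c("+", "-")] <- "*"
    x$strand <- s
  }
  validate_intervals(x)
  x
}

#' Write intervals as BED6
#'
#' @param x interval data.frame (`name`/`score` columns used when present).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- x$name %||% rep(".", nrow(x))
  score <- x$score %||% rep(0, nrow(x))
  strand <- x$strand %||% rep("*", nrow(x))
  strand <- ifelse(strand %in% c("+", "-"), strand, ".")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   as.character(name), format(score, trim = TRUE,
                                              scientific = FALSE),
                   strand)
  writeLines(lines, path)
  invisible(path)
}

#' All overlapping query/subject pairs
#'
#' A pair is reported iff the two intervals share at least one base
#' (BEDTools `intersect` default). With `strand_aware = TRUE` strands must be
#' compatible; an unstranded interval matches either strand. Output is
#' ordered by query row, then subject start.
#'
#' @param query,subject interval data.frames.
#' @param strand_aware require strand compatibility.
#' @return data.frame with columns `query` and `subject` (row indices).
#' @export
intersect_intervals <- function(query, subject, strand_aware = FALSE) {
  validate_intervals(query)
  validate_intervals(subject)
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(), subject = integer()))
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                      ignore.strand = !strand_aware)
  out <- data.frame(query = S4Vectors::queryHits(hits),
                    subject = S4Vectors::subjectHits(hits))
  out[order(out$query, subject$start[out$subject], out$subject), ,
      drop = FALSE]
}

#' Merge overlapping intervals
#'
#' Collapses intervals sharing at least one base into their union. With
#' `strand_aware = TRUE` merging is done per strand. Half-open abutting
#' intervals (`end == start`) are *not* merged, matching the >= 1 shared base
#' overlap rule used everywhere in the package.
#'
#' @param x interval data.frame.
#' @param strand_aware merge per strand.
#' @return merged interval data.frame.
#' @export
merge_intervals <- function(x, strand_aware = FALSE) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end", "strand")])
  gr <- as_granges(x)
  red <- GenomicRanges::reduce(gr, ignore.strand = !strand_aware,
                               min.gapwidth = 0L)
  out <- from_granges(red)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}
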