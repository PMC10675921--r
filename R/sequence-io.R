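# Sequence and track file I/O: FASTA, FASTQ pairs, SAM (text), bedGraph and
# fixedStep WIG score tracks.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; contig order follows the file.
#'
#' @param path FASTA file.
#' @return named character vector (a "genome"): contig name -> sequence.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(), character()))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stopf("FASTA parse error in '%s': %s",
                                            path, conditionMessage(e)))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) stopf("duplicate contig name in '%s'", path)
  if (any(nchar(seqs) == 0)) stopf("zero-length sequence in '%s'", path)
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param genome named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a per-base score track (bedGraph or fixedStep WIG)
#'
#' Scores (e.g. phastCons conservation probabilities) must lie in [0, 1].
#' WIG fixedStep coordinates are 1-based and converted to the package's
#' 0-based convention on read. Overlapping spans with conflicting values are
#' an error.
#'
#' @param path track file.
#' @param format `"bedgraph"` or `"wig_fixed"`.
#' @return a `score_track` object supporting [score_at()].
#' @export
read_score_track <- function(path, format = c("bedgraph", "wig_fixed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  spans <- if (format == "bedgraph") parse_bedgraph(lines)
           else parse_wig_fixed(lines)
  if (nrow(spans) && (any(spans$value < 0) || any(spans$value > 1)))
    stopf("score outside [0,1] in '%s'", path)
  track <- split(spans[, c("start", "end", "value")], spans$chrom)
  track <- lapply(track, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    ov <- which(d$start[-1] < d$end[-nrow(d)])
    if (length(ov)) {
      conflict <- abs(d$value[ov] - d$value[ov + 1]) > 1e-12
      if (any(conflict))
        stopf("overlapping spans with conflicting values near position %d",
              d$start[ov[which(conflict)[1]] + 1])
      # identical-value overlap: clip to keep spans disjoint
      d$end[ov] <- d$start[ov + 1]
      d <- d[d$start < d$end, , drop = FALSE]
    }
    d
  })
  structure(list(spans = track), class = "score_track")
}

parse_bedgraph <- function(lines) {
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  f <- strsplit(lines, "[ \t]+")
  if (any(lengths(f) < 4)) stopf("bedGraph line with fewer than 4 fields")
  data.frame(chrom = vapply(f, `[[`, "", 1),
             start = as.numeric(vapply(f, `[[`, "", 2)),
             end = as.numeric(vapply(f, `[[`, "", 3)),
             value = as.numeric(vapply(f, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

parse_wig_fixed <- function(lines) {
  out <- list()
  chrom <- NULL; pos0 <- NA; step <- 1; span <- 1
  for (ln in lines) {
    if (startsWith(ln, "fixedStep")) {
      get <- function(key, default = NA) {
        m <- regmatches(ln, regexpr(paste0(key, "=[^ \t]+"), ln))
        if (!length(m)) return(default)
        sub(paste0(key, "="), "", m)
      }
      chrom <- get("chrom")
      if (is.na(chrom)) stopf("fixedStep header without chrom=")
      pos0 <- as.numeric(get("start")) - 1  # WIG is 1-based
      step <- as.numeric(get("step", "1"))
      span <- as.numeric(get("span", "1"))
    } else {
      if (is.null(chrom)) stopf("WIG data line before fixedStep header")
      v <- as.numeric(ln)
      if (is.na(v)) stopf("non-numeric WIG value: '%s'", ln)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, start = pos0,
                                           end = pos0 + span, value = v,
                                           stringsAsFactors = FALSE)
      pos0 <- pos0 + step
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  do.call(rbind, out)
}

#' Per-base score lookup
#'
#' @param track a `score_track` from [read_score_track()].
#' @param chrom contig name (scalar).
#' @param pos 0-based positions (vector).
#' @return numeric vector of scores; `NA` where the track has no data.
#' @export
score_at <- function(track, chrom, pos) {
  stopifnot(inherits(track, "score_track"))
  d <- track$spans[[chrom]]
  if (is.null(d)) return(rep(NA_real_, length(pos)))
  idx <- findInterval(pos, d$start)
  ok <- idx >= 1 & idx <= nrow(d)
  ok[ok] <- pos[ok] < d$end[idx[ok]]
  out <- rep(NA_real_, length(pos))
  out[ok] <- d$value[idx[ok]]
  out
}

#' Read paired FASTQ files
#'
#' Mates are matched by file order (record i of file 1 pairs record i of
#' file 2), the Illumina convention for split paired-end FASTQ.
#'
#' @param path1,path2 FASTQ paths for read 1 and read 2.
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (qualities as Phred+33 strings).
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2))
    stopf("paired FASTQ files differ in record count (%d vs %d)",
          nrow(r1), nrow(r2))
  data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

read_fastq_one <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(id = character(), seq = character(),
                      qual = character()))
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(set)),
             seq = as.character(set),
             qual = as.character(S4Vectors::mcols(set)$qualities),
             stringsAsFactors = FALSE)
}

#' Write paired FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param path1,path2 output FASTQ paths.
#' @return invisibly, `c(path1, path2)`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  writeLines(as.vector(rbind(paste0("@", pairs$id), pairs$seq1,
                             "+", pairs$qual1)), path1)
  writeLines(as.vector(rbind(paste0("@", pairs$id), pairs$seq2,
                             "+", pairs$qual2)), path2)
  invisible(c(path1, path2))
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
      stopf("malformed CIGAR '%s'", cg)
    n <- as.numeric(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read paired alignments from a SAM text file
#'
#' Minimal column reader for headered or headerless SAM at desk scale
#' (binary BAM is out of scope). Secondary (0x100) and supplementary (0x800)
#' records are dropped; mates are matched by query name and first/second
#' flags. Coordinates are converted to 0-based half-open.
#'
#' @param path SAM file.
#' @return data.frame of aligned mates: `pair_id`, `mate` (1 or 2), `chrom`,
#'   `start`, `end`, `strand`, `mapq`, `mapped`.
#' @export
read_sam_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(pair_id = character(), mate = integer(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), mapq = numeric(),
                      mapped = logical()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11)) stopf("SAM line with fewer than 11 fields")
  flag <- as.integer(vapply(f, `[[`, "", 2))
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  f <- f[keep]; flag <- flag[keep]
  pos1 <- as.numeric(vapply(f, `[[`, "", 4))
  cigar <- vapply(f, `[[`, "", 6)
  mapped <- bitwAnd(flag, 0x4L) == 0L & pos1 > 0 & cigar != "*"
  width <- ifelse(mapped, cigar_ref_width(cigar), 0)
  data.frame(
    pair_id = vapply(f, `[[`, "", 1),
    mate = ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 1L),
    chrom = vapply(f, `[[`, "", 3),
    start = pos1 - 1,
    end = pos1 - 1 + width,
    strand = ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
    mapq = as.numeric(vapply(f, `[[`, "", 5)),
    mapped = mapped,
    stringsAsFactors = FALSE)
}

#' Write paired alignments as SAM text
#'
#' Emits one proper-pair record per mate with `*` SEQ/QUAL placeholders
#' (coordinates, strand, MAPQ and CIGAR carry all information the insertion
#' caller consumes).
#'
#' @param pairs data.frame in the layout returned by [read_sam_pairs()].
#' @param path output path.
#' @param contig_lengths named vector for the `@SQ` header lines.
#' @return invisibly, `path`.
#' @export
write_sam_pairs <- function(pairs, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  mate_of <- ifelse(pairs$mate == 1L, 2L, 1L)
  key <- paste(pairs$pair_id, pairs$mate)
  mkey <- paste(pairs$pair_id, mate_of)
  midx <- match(mkey, key)
  flag <- 0x1L + 0x2L +
    ifelse(pairs$mate == 1L, 0x40L, 0x80L) +
    ifelse(pairs$strand == "-", 0x10L, 0L) +
    ifelse(!is.na(midx) & pairs$strand[midx] == "-", 0x20L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t0\t*\t*",
                     pairs$pair_id, flag, pairs$chrom,
                     as.integer(pairs$start + 1), as.integer(pairs$mapq),
                     as.integer(pairs$end - pairs$start),
                     as.integer(ifelse(is.na(midx), pairs$start,
                                       pairs$start[midx]) + 1)),
             con)
  invisible(path)
}
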