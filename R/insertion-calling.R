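# Insertion-site calling from LTR-junction paired-end libraries.
#
# Library structure: read 2 begins with the proviral LTR tag followed by the
# genomic sequence flanking the integration site; read 1 is the genomic mate.
# The pipeline keeps only pairs whose read 2 starts with the exact tag and
# whose every base exceeds the Phred cutoff, trims the tag, aligns the
# trimmed reads (externally; alignments come back as SAM), and places the
# insertion at the first genomic base upstream of the LTR tag.

#' The 68-nt lentiviral LTR junction tag
#'
#' Default tag that read 2 of a junction library must start with.
#'
#' @return character scalar (68 nt).
#' @export
inset_ltr_tag <- function() {
  paste0("GCCTTGTGTGTGGTAGATCCACAGATCAAGGATATCTTGTCTTCGTTGGG",
         "AGTGAATTAGCCCTTCCA")
}

#' Filter read pairs on the LTR tag and base qualities
#'
#' A pair is retained iff read 2 begins with `ltr_tag` exactly (no
#' mismatches) and every base of both mates has Phred quality strictly
#' greater than `min_phred`. Retained rows are returned unchanged (so the
#' filter is idempotent) with the tag-trimmed read 2 added as `seq2_trim` /
#' `qual2_trim`, ready for alignment.
#'
#' @param pairs data.frame from [read_fastq_pairs()].
#' @param ltr_tag tag sequence; default [inset_ltr_tag()].
#' @param min_phred quality cutoff (strict inequality); default 20.
#' @return retained pairs (read 2 trimmed), with a named integer attribute
#'   `"rejections"` counting dropped pairs by reason
#'   (`too_short`, `no_tag`, `low_quality`).
#' @export
filter_ltr_pairs <- function(pairs, ltr_tag = inset_ltr_tag(),
                             min_phred = 20) {
  stopifnot(is.data.frame(pairs), nchar(ltr_tag) > 0)
  if (nrow(pairs) == 0) {
    attr(pairs, "rejections") <- c(too_short = 0L, no_tag = 0L,
                                   low_quality = 0L)
    return(pairs)
  }
  tag_len <- nchar(ltr_tag)
  too_short <- nchar(pairs$seq2) < tag_len
  has_tag <- !too_short & substr(pairs$seq2, 1, tag_len) == ltr_tag
  minq <- pmin(min_phred_of(pairs$qual1), min_phred_of(pairs$qual2))
  good_q <- minq > min_phred
  keep <- has_tag & good_q
  out <- pairs[keep, , drop = FALSE]
  out$seq2_trim <- substr(out$seq2, tag_len + 1, nchar(out$seq2))
  out$qual2_trim <- substr(out$qual2, tag_len + 1, nchar(out$qual2))
  attr(out, "rejections") <- c(
    too_short = sum(too_short),
    no_tag = sum(!too_short & !has_tag),
    low_quality = sum(has_tag & !good_q))
  rownames(out) <- NULL
  out
}

# Minimum Phred score over a Phred+33 quality string (empty string -> Inf).
min_phred_of <- function(qual) {
  vapply(qual, function(q) {
    if (!nchar(q)) return(Inf)
    min(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Call insertion positions from aligned read pairs
#'
#' Read 2 must have been tag-trimmed before alignment, so its tag-proximal
#' alignment end abuts the integration site. A pair is retained iff both
#' mates are uniquely mapped (`mapped` and `mapq >= min_mapq`), on the same
#' contig, on opposing strands, with outer span at most `max_span`. The
#' insertion position is the genomic base adjacent to the tag-proximal end of
#' read 2's alignment: alignment start - 1 for read 2 on "+", alignment end
#' (as a 0-based point) on "-". Positions outside contig bounds are dropped.
#'
#' @param aligned_pairs data.frame from [read_sam_pairs()].
#' @param min_mapq minimum mapping quality; default 30.
#' @param max_span maximum outer pair span in bp; default 1000.
#' @param contig_lengths named numeric vector of contig lengths (used for the
#'   bounds check; optional).
#' @return data.frame of per-pair insertion points: `pair_id`, `chrom`,
#'   `pos`, `strand` (read 2 strand, recording provirus orientation), with a
#'   `"rejections"` attribute counting dropped pairs by reason.
#' @export
call_insertion_sites <- function(aligned_pairs, min_mapq = 30,
                                 max_span = 1000, contig_lengths = NULL) {
  a <- aligned_pairs
  r1 <- a[a$mate == 1L, , drop = FALSE]
  r2 <- a[a$mate == 2L, , drop = FALSE]
  ids <- intersect(r1$pair_id, r2$pair_id)
  rej <- c(unpaired = nrow(r1) + nrow(r2) - 2L * length(ids),
           not_unique = 0L, different_contig = 0L, same_strand = 0L,
           span_too_large = 0L, out_of_bounds = 0L)
  r1 <- r1[match(ids, r1$pair_id), , drop = FALSE]
  r2 <- r2[match(ids, r2$pair_id), , drop = FALSE]

  uniq <- r1$mapped & r2$mapped & r1$mapq >= min_mapq & r2$mapq >= min_mapq
  rej["not_unique"] <- sum(!uniq)
  same_chrom <- uniq & r1$chrom == r2$chrom
  rej["different_contig"] <- sum(uniq & !same_chrom)
  opposed <- same_chrom & r1$strand != r2$strand
  rej["same_strand"] <- sum(same_chrom & !opposed)
  span <- pmax(r1$end, r2$end) - pmin(r1$start, r2$start)
  ok_span <- opposed & span <= max_span
  rej["span_too_large"] <- sum(opposed & !ok_span)

  pos <- ifelse(r2$strand == "+", r2$start - 1, r2$end)
  in_bounds <- pos >= 0
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[r2$chrom]
    in_bounds <- in_bounds & !is.na(len) & pos < len
  }
  keep <- ok_span & in_bounds
  rej["out_of_bounds"] <- sum(ok_span & !in_bounds)

  out <- data.frame(pair_id = ids[keep], chrom = r2$chrom[keep],
                    pos = pos[keep], strand = r2$strand[keep],
                    stringsAsFactors = FALSE)
  attr(out, "rejections") <- rej
  out
}

#' Accumulate per-pair insertion positions into a count matrix
#'
#' One row per unique (contig, position); one raw-count column per sample.
#' The per-sample library size is the number of retained aligned pairs.
#'
#' @param positions data.frame with `chrom` and `pos` (one row per retained
#'   pair), e.g. from [call_insertion_sites()].
#' @param sample_id sample name for the new column.
#' @param existing an existing `insertion_matrix` to extend, or `NULL`.
#' @param lib_size library size to record; defaults to `nrow(positions)`.
#' @return an `insertion_matrix`: list with `sites` (chrom, pos, strand),
#'   `counts` (sites x samples), `lib_sizes`, and `norm` (filled by
#'   [normalize_depth()]).
#' @export
aggregate_counts <- function(positions, sample_id, existing = NULL,
                             lib_size = nrow(positions)) {
  strand <- positions$strand %||% rep("*", nrow(positions))
  key <- site_key(positions$chrom, positions$pos)
  tab <- table(key)

  if (is.null(existing)) {
    sites <- data.frame(chrom = character(), pos = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
    counts <- matrix(0, 0, 0)
    lib_sizes <- numeric()
  } else {
    stopifnot(inherits(existing, "insertion_matrix"))
    sites <- existing$sites; counts <- existing$counts
    lib_sizes <- existing$lib_sizes
    if (sample_id %in% names(lib_sizes))
      stopf("sample '%s' already present", sample_id)
  }
  old_keys <- site_key(sites$chrom, sites$pos)
  new_keys <- setdiff(names(tab), old_keys)
  if (length(new_keys)) {
    first <- match(new_keys, key)
    sites <- rbind(sites, data.frame(chrom = positions$chrom[first],
                                     pos = positions$pos[first],
                                     strand = strand[first],
                                     stringsAsFactors = FALSE))
    counts <- rbind(counts, matrix(0, length(new_keys), ncol(counts)))
  }
  all_keys <- site_key(sites$chrom, sites$pos)
  col <- numeric(nrow(sites))
  col[match(names(tab), all_keys)] <- as.numeric(tab)
  counts <- cbind(counts, col)
  colnames(counts) <- c(names(lib_sizes), sample_id)
  lib_sizes <- c(lib_sizes, stats::setNames(lib_size, sample_id))

  ord <- order(sites$chrom, sites$pos)
  new_insertion_matrix(sites[ord, , drop = FALSE],
                       counts[ord, , drop = FALSE], lib_sizes)
}

# paste0 recycles zero-length inputs against scalars; keep keys length-safe
site_key <- function(chrom, pos) {
  if (length(chrom) == 0) return(character())
  paste0(chrom, ":", pos)
}

new_insertion_matrix <- function(sites, counts, lib_sizes, norm = NULL) {
  rownames(sites) <- NULL
  rownames(counts) <- NULL
  structure(list(sites = sites, counts = counts, lib_sizes = lib_sizes,
                 norm = norm),
            class = "insertion_matrix")
}

#' @export
print.insertion_matrix <- function(x, ...) {
  cat(sprintf("insertion_matrix: %d sites x %d samples%s\n",
              nrow(x$sites), ncol(x$counts),
              if (is.null(x$norm)) "" else " (normalized)"))
  cat("library sizes:", paste(names(x$lib_sizes), x$lib_sizes,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Depth normalization to counts per million aligned pairs
#'
#' Normalized depth = raw count x 1e6 / library size (CPM). CPM keeps every
#' observable nonzero depth well above the log10 zero floor used downstream.
#'
#' @param matrix an `insertion_matrix`.
#' @return the matrix with its `norm` slot filled.
#' @export
normalize_depth <- function(matrix) {
  stopifnot(inherits(matrix, "insertion_matrix"))
  zero_lib <- matrix$lib_sizes == 0
  if (any(zero_lib & colSums(matrix$counts) > 0))
    stopf("sample '%s' has zero library size but nonzero counts",
          names(matrix$lib_sizes)[zero_lib & colSums(matrix$counts) > 0][1])
  scale <- ifelse(zero_lib, 0, 1e6 / matrix$lib_sizes)
  matrix$norm <- sweep(matrix$counts, 2, scale, `*`)
  matrix
}

#' Write an insertion matrix as TSV
#'
#' Columns: chrom, pos, strand, then `<sample>.count` and `<sample>.cpm` per
#' sample; library sizes in a `#lib_sizes` header comment.
#'
#' @param matrix an `insertion_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_insertion_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "insertion_matrix"))
  m <- if (is.null(matrix$norm)) normalize_depth(matrix) else matrix
  df <- cbind(m$sites,
              stats::setNames(as.data.frame(m$counts),
                              paste0(colnames(m$counts), ".count")),
              stats::setNames(as.data.frame(m$norm),
                              paste0(colnames(m$norm), ".cpm")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#lib_sizes\t",
                    paste(names(m$lib_sizes), m$lib_sizes, sep = "=",
                          collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an insertion matrix written by [write_insertion_matrix()]
#'
#' @param path TSV path.
#' @return an `insertion_matrix`.
#' @export
read_insertion_matrix <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#lib_sizes"))
    stopf("'%s' is not an insertion-matrix TSV", path)
  kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=", fixed = TRUE)
  lib_sizes <- stats::setNames(as.numeric(vapply(kv, `[[`, "", 2)),
                               vapply(kv, `[[`, "", 1))
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  count_cols <- grep("\\.count$", names(df), value = TRUE)
  cpm_cols <- grep("\\.cpm$", names(df), value = TRUE)
  counts <- as.matrix(df[count_cols])
  colnames(counts) <- sub("\\.count$", "", count_cols)
  norm <- as.matrix(df[cpm_cols])
  colnames(norm) <- sub("\\.cpm$", "", cpm_cols)
  new_insertion_matrix(df[c("chrom", "pos", "strand")], counts,
                       lib_sizes[colnames(counts)], norm)
}
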