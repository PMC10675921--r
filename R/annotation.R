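# Hierarchical genomic annotation of insertion calls, element density/depth
# metrics, enrichment odds ratios, TSS distance bins, and conservation at
# insertion sites.
#
# Every position is assigned to exactly one category: the first category in
# the hierarchy whose interval set contains it wins. The default order goes
# from the most confidently functional annotation (coding exons) down to
# gene deserts.

#' Category order of the annotation hierarchy
#'
#' @return character vector of category names, most specific first.
#' @export
annotation_categories <- function() {
  c("EXON_CODING", "EXON_LNCRNA", "VLINCRNA", "PROMOTER", "ENHANCER",
    "INSULATOR", "TSS_UP_0_5K", "TSS_UP_5_10K", "TSS_DOWN_0_5K",
    "TSS_DOWN_5_10K", "GENSCAN_INTRONIC", "GENSCAN_INTERGENIC",
    "INTRON_OTHER", "INTERGENIC_OTHER", "GENE_DESERT")
}

#' Build an annotation hierarchy
#'
#' @param sets named list of interval data.frames for the direct annotation
#'   layers; recognized names: `exon_coding`, `exon_lncrna`, `vlincrna`,
#'   `promoter`, `enhancer`, `insulator`, `genscan_exon`. Missing layers are
#'   treated as empty.
#' @param genes gene models: data.frame with `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (one row per gene; the longest transcript per gene).
#' @param exons exon intervals of those transcripts: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param genome_lengths named contig lengths (used to validate positions).
#' @param order category order; default [annotation_categories()].
#' @param desert_margin distance from any gene boundary that defines a gene
#'   desert, in bp; default 50000.
#' @param tss_bins distance-bin breaks from a TSS, in bp; default
#'   `c(5000, 10000)` giving 0-5 kb and 5-10 kb bins.
#' @return list of class `annotation_hierarchy`.
#' @export
annotation_hierarchy <- function(sets, genes, exons,
                                 genome_lengths = NULL,
                                 order = annotation_categories(),
                                 desert_margin = 50000,
                                 tss_bins = c(5000, 10000)) {
  known <- c("exon_coding", "exon_lncrna", "vlincrna", "promoter",
             "enhancer", "insulator", "genscan_exon")
  bad <- setdiff(names(sets), known)
  if (length(bad)) stopf("unknown annotation layer(s): %s",
                         paste(bad, collapse = ", "))
  empty <- gintervals(character(), numeric(), numeric())[0, ]
  sets <- lapply(stats::setNames(nm = known),
                 function(nm) sets[[nm]] %||% empty)
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  # TSS: first transcribed base along the gene's orientation
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  gene_spans <- genes[, c("chrom", "start", "end", "strand")]
  gsc <- sets$genscan_exon
  if (nrow(gsc)) {
    in_gene <- unique(intersect_intervals(gsc, gene_spans)$query)
    sets$genscan_intronic <- gsc[in_gene, , drop = FALSE]
    sets$genscan_intergenic <- gsc[setdiff(seq_len(nrow(gsc)), in_gene),
                                   , drop = FALSE]
  } else {
    sets$genscan_intronic <- sets$genscan_intergenic <- empty
  }
  structure(list(sets = sets, genes = genes, exons = exons,
                 genome_lengths = genome_lengths, order = order,
                 desert_margin = desert_margin, tss_bins = tss_bins),
            class = "annotation_hierarchy")
}

# positions df(chrom,pos) -> logical: inside any interval of `set`.
pos_in_set <- function(positions, set) {
  if (nrow(set) == 0 || nrow(positions) == 0)
    return(rep(FALSE, nrow(positions)))
  pts <- gintervals(positions$chrom, positions$pos, positions$pos + 1)
  hits <- intersect_intervals(pts, set)
  out <- rep(FALSE, nrow(positions))
  out[unique(hits$query)] <- TRUE
  out
}

#' Distance bin from the nearest qualifying TSS
#'
#' Distance is measured along the gene's orientation from each annotated
#' TSS. A position downstream of a TSS that falls inside any exon of that
#' gene does not qualify for that gene (exonic insertions are counted in the
#' exon categories, not the downstream bins). Among qualifying gene TSSs the
#' nearest wins.
#'
#' @param positions data.frame with `chrom`, `pos`.
#' @param hierarchy an [annotation_hierarchy()].
#' @return character vector: one of `TSS_UP_0_5K`, `TSS_UP_5_10K`,
#'   `TSS_DOWN_0_5K`, `TSS_DOWN_5_10K`, or `NA` when no TSS is within the
#'   outermost bin.
#' @export
tss_distance_bin <- function(positions, hierarchy) {
  genes <- hierarchy$genes
  exons <- hierarchy$exons
  max_d <- max(hierarchy$tss_bins)
  mid_d <- hierarchy$tss_bins[1]
  n <- nrow(positions)
  out <- rep(NA_character_, n)
  if (n == 0 || nrow(genes) == 0) return(out)

  # candidate gene TSSs within max_d of each position
  tss_win <- gintervals(genes$chrom, pmax(0, genes$tss - max_d),
                        genes$tss + max_d + 1)
  pts <- gintervals(positions$chrom, positions$pos, positions$pos + 1)
  hits <- intersect_intervals(pts, tss_win)
  if (nrow(hits) == 0) return(out)

  g <- genes[hits$subject, ]
  p <- positions$pos[hits$query]
  signed <- ifelse(g$strand == "-", g$tss - p, p - g$tss)  # >0 downstream
  dist <- abs(signed)
  ok <- dist >= 1 & dist <= max_d

  # downstream positions inside an exon of the candidate gene do not qualify
  down <- ok & signed > 0
  if (any(down)) {
    idx <- which(down)
    exon_hit <- mapply(function(q, gid) {
      e <- exons[exons$gene_id == gid, , drop = FALSE]
      any(e$start <= positions$pos[q] & positions$pos[q] < e$end &
            e$chrom == positions$chrom[q])
    }, hits$query[idx], g$gene_id[idx])
    ok[idx][exon_hit] <- FALSE
  }
  if (!any(ok)) return(out)

  cand <- data.frame(query = hits$query[ok], dist = dist[ok],
                     signed = signed[ok])
  best <- cand[order(cand$query, cand$dist), ]
  best <- best[!duplicated(best$query), ]
  bin <- ifelse(best$signed < 0,
                ifelse(best$dist <= mid_d, "TSS_UP_0_5K", "TSS_UP_5_10K"),
                ifelse(best$dist <= mid_d, "TSS_DOWN_0_5K", "TSS_DOWN_5_10K"))
  out[best$query] <- bin
  out
}

#' Assign each position to exactly one genomic category
#'
#' Walks the hierarchy order; the first interval set containing the position
#' wins. Intronic positions not claimed earlier become `INTRON_OTHER`;
#' intergenic positions at least `desert_margin` bp from every gene boundary
#' become `GENE_DESERT`, the remainder `INTERGENIC_OTHER`.
#'
#' @param positions data.frame with `chrom`, `pos`.
#' @param hierarchy an [annotation_hierarchy()].
#' @return character vector of category names, one per position.
#' @export
assign_category <- function(positions, hierarchy) {
  h <- hierarchy
  n <- nrow(positions)
  if (!is.null(h$genome_lengths)) {
    bad <- !positions$chrom %in% names(h$genome_lengths)
    if (any(bad)) stopf("position on unknown contig '%s'",
                        positions$chrom[bad][1])
  }
  out <- rep(NA_character_, n)
  layer_sets <- list(
    EXON_CODING = h$sets$exon_coding, EXON_LNCRNA = h$sets$exon_lncrna,
    VLINCRNA = h$sets$vlincrna, PROMOTER = h$sets$promoter,
    ENHANCER = h$sets$enhancer, INSULATOR = h$sets$insulator,
    GENSCAN_INTRONIC = h$sets$genscan_intronic,
    GENSCAN_INTERGENIC = h$sets$genscan_intergenic)
  tss_cats <- c("TSS_UP_0_5K", "TSS_UP_5_10K", "TSS_DOWN_0_5K",
                "TSS_DOWN_5_10K")
  tss_bin <- NULL
  gene_spans <- h$genes[, c("chrom", "start", "end")]

  for (cat in h$order) {
    open <- is.na(out)
    if (!any(open)) break
    sub <- positions[open, , drop = FALSE]
    if (cat %in% names(layer_sets)) {
      hit <- pos_in_set(sub, layer_sets[[cat]])
      out[open][hit] <- cat
    } else if (cat %in% tss_cats) {
      if (is.null(tss_bin)) tss_bin <- tss_distance_bin(positions, h)
      out[open][tss_bin[open] %in% cat] <- cat
    } else if (cat == "INTRON_OTHER") {
      hit <- pos_in_set(sub, cbind(gene_spans, strand = "*"))
      out[open][hit] <- cat
    } else if (cat %in% c("INTERGENIC_OTHER", "GENE_DESERT")) {
      # handled together from the gene-distance rule
      if (nrow(gene_spans)) {
        pts <- as_granges(gintervals(sub$chrom, sub$pos, sub$pos + 1))
        gg <- as_granges(cbind(gene_spans, strand = "*"))
        dd <- GenomicRanges::distanceToNearest(pts, gg, ignore.strand = TRUE)
        dist <- rep(Inf, nrow(sub))
        dist[S4Vectors::queryHits(dd)] <- S4Vectors::mcols(dd)$distance
      } else dist <- rep(Inf, nrow(sub))
      desert <- dist >= h$desert_margin
      if (cat == "GENE_DESERT") out[open][desert] <- "GENE_DESERT"
      else out[open][!desert] <- "INTERGENIC_OTHER"
    } else stopf("unknown category '%s' in hierarchy order", cat)
  }
  out[is.na(out)] <- "INTERGENIC_OTHER"
  out
}

#' Insertion density and average depth within an element set
#'
#' Density is unique insertion positions per megabase of element sequence.
#' Average depth is the mean raw count over those positions after removing
#' outlier positions with count >= `outlier_cutoff`.
#'
#' @param matrix an `insertion_matrix`.
#' @param elements interval data.frame of the element set.
#' @param outlier_cutoff positions at or above this raw count are removed
#'   before averaging; default 10000.
#' @return data.frame, one row per sample: `sample`, `n_positions`,
#'   `density_per_mb`, `avg_depth` (NA when no positions overlap).
#' @export
density_and_depth <- function(matrix, elements, outlier_cutoff = 10000) {
  stopifnot(inherits(matrix, "insertion_matrix"))
  validate_intervals(elements)
  if (nrow(elements) == 0) stopf("empty element set")
  mb <- sum(merge_intervals(elements)$end -
              merge_intervals(elements)$start) / 1e6
  if (mb == 0) stopf("element set covers zero bases")
  inside <- pos_in_set(matrix$sites[, c("chrom", "pos")], elements)
  samples <- colnames(matrix$counts)
  do.call(rbind, lapply(samples, function(s) {
    cnt <- matrix$counts[, s]
    present <- inside & cnt > 0
    depths <- cnt[present]
    depths <- depths[depths < outlier_cutoff]
    data.frame(sample = s, n_positions = sum(present),
               density_per_mb = sum(present) / mb,
               avg_depth = if (length(depths)) mean(depths) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Odds ratio of phenotypic vs non-phenotypic insertions in an element set
#'
#' `OR = (a/b) / (c/d)` with a/b phenotypic positions inside/outside the
#' element set and c/d the same for non-phenotypic positions. With
#' `haldane = TRUE`, 0.5 is added to every cell whenever any cell is zero.
#'
#' @param pheno_positions,nonpheno_positions data.frames with `chrom`,
#'   `pos`.
#' @param elements interval data.frame.
#' @param haldane apply the Haldane-Anscombe correction on zero cells.
#' @return list with `or` and the 2x2 `table` (a, b, c, d).
#' @export
odds_ratio <- function(pheno_positions, nonpheno_positions, elements,
                       haldane = TRUE) {
  if (nrow(pheno_positions) == 0 || nrow(nonpheno_positions) == 0)
    stopf("both position sets must be non-empty")
  a <- sum(pos_in_set(pheno_positions, elements))
  b <- nrow(pheno_positions) - a
  c_ <- sum(pos_in_set(nonpheno_positions, elements))
  d <- nrow(nonpheno_positions) - c_
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells == 0)) {
    if (!haldane) return(list(or = NA_real_, table = cells))
    cells <- cells + 0.5
  }
  list(or = unname((cells["a"] / cells["b"]) / (cells["c"] / cells["d"])),
       table = cells)
}

#' Conservation scores flanking insertion sites
#'
#' Positions overlapping any exclusion set are dropped. For each retained
#' position the score is the mean of the two immediately adjacent bases
#' (position - 1 and position + 1); a flank without track data is skipped
#' and positions with both flanks missing are dropped.
#'
#' @param positions data.frame with `chrom`, `pos`.
#' @param track a `score_track` (e.g. phastCons) from [read_score_track()].
#' @param exclusion_sets list of interval data.frames to exclude (e.g.
#'   annotated exons, 10 kb TSS neighborhoods).
#' @return data.frame of retained positions with a `score` column.
#' @export
conservation_at_sites <- function(positions, track,
                                  exclusion_sets = list()) {
  keep <- rep(TRUE, nrow(positions))
  for (ex in exclusion_sets) keep <- keep & !pos_in_set(positions, ex)
  pos <- positions[keep, , drop = FALSE]
  if (nrow(pos) == 0) return(cbind(pos, score = numeric(0)))
  score <- vapply(seq_len(nrow(pos)), function(i) {
    fl <- score_at(track, pos$chrom[i], c(pos$pos[i] - 1, pos$pos[i] + 1))
    if (all(is.na(fl))) NA_real_ else mean(fl, na.rm = TRUE)
  }, numeric(1))
  out <- cbind(pos, score = score)
  out <- out[!is.na(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided paired comparison of per-system mean scores
#'
#' Paired one-sided t test on system-level means (alternative: group A
#' greater than group B), the comparison used for conservation of phenotypic
#' vs non-phenotypic insertions across assay systems.
#'
#' @param values_a,values_b numeric vectors paired by system (e.g. one mean
#'   per assay system per group).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
compare_group_scores <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stopf("groups must be paired (equal length)")
  if (length(values_a) < 2) stopf("need at least 2 paired systems")
  d <- values_a - values_b
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  if (s < .Machine$double.eps * max(1, abs(m))) {
    p <- if (abs(m) < .Machine$double.eps) 0.5
         else if (m > 0) .Machine$double.xmin else 1
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1, p = p,
                mean_diff = m))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = stats::pt(t, n - 1, lower.tail = FALSE),
       mean_diff = m)
}
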