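# CAGE-based validation of candidate transcription start sites.
#
# Candidate TSSs (e.g. from 5' RACE) are extended by +/-10 bp on their
# strand, merged into clusters, categorized by a hierarchical region rule,
# and compared with CAGE tag atlases against a composition-matched shuffle
# null: simulated clusters preserve the real clusters' region composition
# (and widths) exactly, at a configurable multiplication factor.

#' Strand-aware TSS windows
#'
#' Each TSS becomes the 21-bp inclusive window \[tss-pad, tss+pad\]
#' (half-open \[tss-pad, tss+pad+1)). Candidates in the immediate vicinity
#' (within `pad` bp, same strand) of an annotated mRNA TSS are dropped so
#' shared known promoters do not confound the validation.
#'
#' @param tss data.frame of candidate TSSs: `chrom`, `pos`, `strand` and
#'   optionally `id`.
#' @param pad half-window in bp; default 10.
#' @param annotated_tss data.frame of annotated mRNA TSSs (`chrom`, `pos`,
#'   `strand`), or `NULL`.
#' @return interval data.frame of windows with `id` and a `truncated` flag
#'   for windows clipped at a contig start.
#' @export
make_tss_windows <- function(tss, pad = 10, annotated_tss = NULL) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tss)))
  keep <- rep(TRUE, nrow(tss))
  if (!is.null(annotated_tss) && nrow(annotated_tss) > 0) {
    for (i in seq_len(nrow(tss))) {
      near <- annotated_tss$chrom == tss$chrom[i] &
        annotated_tss$strand == tss$strand[i] &
        abs(annotated_tss$pos - tss$pos[i]) <= pad
      if (any(near)) keep[i] <- FALSE
    }
  }
  t2 <- tss[keep, , drop = FALSE]
  if (nrow(t2) == 0)
    return(gintervals(character(), numeric(), numeric(),
                      id = character(), truncated = logical())[0, ])
  start <- t2$pos - pad
  truncated <- start < 0
  out <- gintervals(t2$chrom, pmax(0, start), t2$pos + pad + 1,
                    strand = t2$strand,
                    id = t2$id %||% as.character(seq_len(nrow(t2))),
                    truncated = truncated)
  rownames(out) <- NULL
  out
}

#' Merge TSS windows into categorized clusters
#'
#' Strand-aware merge of overlapping windows, then hierarchical region
#' categorization: a cluster overlapping a same-strand exon is `exon`; else
#' a same-strand gene span makes it `intron`; else an opposite-strand gene
#' span makes it `antisense_intragenic`; else `intergenic`.
#'
#' @param windows windows from [make_tss_windows()].
#' @param exons exon intervals with strand.
#' @param genes gene spans with strand.
#' @return data.frame of clusters with a `category` column.
#' @export
cluster_tss_windows <- function(windows, exons, genes) {
  merged <- merge_intervals(windows, strand_aware = TRUE)
  if (nrow(merged) == 0) return(cbind(merged, category = character(0)))
  category <- rep("intergenic", nrow(merged))
  flip <- function(x) {
    x$strand <- c("+" = "-", "-" = "+", "*" = "*")[x$strand]
    x
  }
  sense_exon <- unique(intersect_intervals(merged, exons,
                                           strand_aware = TRUE)$query)
  sense_gene <- unique(intersect_intervals(merged, genes,
                                           strand_aware = TRUE)$query)
  anti_gene <- unique(intersect_intervals(merged, flip(genes),
                                          strand_aware = TRUE)$query)
  category[anti_gene] <- "antisense_intragenic"
  category[setdiff(sense_gene, sense_exon)] <- "intron"
  category[sense_exon] <- "exon"
  merged$category <- category
  merged
}

#' Composition-matched shuffled TSS clusters
#'
#' For each real cluster, `factor` simulated clusters of identical width and
#' random strand are placed uniformly within the cluster's region category,
#' so per-category counts equal `factor` times the real counts exactly.
#'
#' @param clusters categorized clusters from [cluster_tss_windows()].
#' @param region_sets named list of interval data.frames defining the
#'   placement space per category (`exon`, `intron`, `antisense_intragenic`,
#'   `intergenic`).
#' @param factor simulated clusters per real cluster; default 20.
#' @param seed optional integer seed.
#' @return data.frame of simulated clusters with `category` and `source`
#'   (row index of the originating real cluster).
#' @export
shuffle_matched <- function(clusters, region_sets, factor = 20,
                            seed = NULL) {
  run <- function() {
    out <- vector("list", nrow(clusters))
    for (i in seq_len(nrow(clusters))) {
      cat_i <- clusters$category[i]
      width <- clusters$end[i] - clusters$start[i]
      space <- region_sets[[cat_i]]
      if (is.null(space) || nrow(space) == 0)
        stopf("no placement space for category '%s'", cat_i)
      room <- (space$end - space$start) - width + 1
      ok <- room > 0
      if (!any(ok))
        stopf("no interval in category '%s' can hold a %d bp cluster",
              cat_i, width)
      sp <- space[ok, , drop = FALSE]
      room <- room[ok]
      pick <- sample.int(nrow(sp), factor, replace = TRUE,
                         prob = room / sum(room))
      offset <- floor(stats::runif(factor) * room[pick])
      out[[i]] <- data.frame(
        chrom = sp$chrom[pick],
        start = sp$start[pick] + offset,
        end = sp$start[pick] + offset + width,
        strand = sample(c("+", "-"), factor, replace = TRUE),
        category = cat_i, source = i, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  if (nrow(clusters) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      category = character(), source = integer()))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Normalized CAGE abundance
#'
#' `C * 1e7 / T`, where C is the tag depth at a CAGE TSS and T the sample's
#' total tag count.
#'
#' @param C tag depth (vector allowed).
#' @param T_total total tags in the sample.
#' @return normalized abundance.
#' @export
normalized_cage_abundance <- function(C, T_total) {
  if (any(T_total <= 0)) stopf("sample total tag count must be positive")
  if (any(C < 0)) stopf("negative CAGE depth")
  C * 1e7 / T_total
}

#' Construct a CAGE sample
#'
#' @param id sample id.
#' @param tags data.frame of CAGE TSS tags: `chrom`, `pos`, `strand`,
#'   `depth`.
#' @param total total tag count T; defaults to `sum(tags$depth)`.
#' @return list of class `cage_sample`.
#' @export
cage_sample <- function(id, tags, total = sum(tags$depth)) {
  stopifnot(all(c("chrom", "pos", "strand", "depth") %in% names(tags)))
  if (total <= 0) stopf("cage_sample '%s': total tag count must be > 0", id)
  structure(list(id = id, tags = tags, total = total),
            class = "cage_sample")
}

#' Per-cluster CAGE signal across samples
#'
#' For each cluster: the number of samples with at least one same-strand
#' tag inside the cluster span, and the summed normalized abundance of the
#' overlapping tags over those samples.
#'
#' @param clusters interval data.frame (stranded).
#' @param samples list of [cage_sample()] objects.
#' @return data.frame: `cluster`, `n_samples`, `abundance`.
#' @export
cluster_signal <- function(clusters, samples) {
  n <- nrow(clusters)
  n_samples <- integer(n)
  abundance <- numeric(n)
  for (s in samples) {
    stopifnot(inherits(s, "cage_sample"))
    tg <- s$tags
    if (nrow(tg) == 0) next
    tag_int <- gintervals(tg$chrom, tg$pos, tg$pos + 1, strand = tg$strand)
    hits <- intersect_intervals(clusters, tag_int, strand_aware = TRUE)
    if (nrow(hits) == 0) next
    per <- tapply(normalized_cage_abundance(tg$depth[hits$subject], s$total),
                  hits$query, sum)
    idx <- as.integer(names(per))
    n_samples[idx] <- n_samples[idx] + 1L
    abundance[idx] <- abundance[idx] + as.numeric(per)
  }
  data.frame(cluster = seq_len(n), n_samples = n_samples,
             abundance = abundance)
}

#' Compare real vs simulated cluster CAGE signal
#'
#' Detected fraction (clusters with >= 1 sample) compared by chi-square on
#' the 2x2 detected/undetected table (Fisher's exact test when the table is
#' degenerate), plus two-sided Wilcoxon rank-sum tests on the full
#' per-cluster distributions (zeros included) of sample counts and
#' normalized abundance.
#'
#' @param real_signals,sim_signals data.frames from [cluster_signal()].
#' @return list: `real_detected_fraction`, `sim_detected_fraction`,
#'   `chisq_p`, `wilcox_n_samples_p`, `wilcox_abundance_p`.
#' @export
compare_real_vs_sim <- function(real_signals, sim_signals) {
  if (nrow(real_signals) == 0 || nrow(sim_signals) == 0)
    stopf("both signal sets must be non-empty")
  rd <- sum(real_signals$n_samples >= 1)
  sd_ <- sum(sim_signals$n_samples >= 1)
  tab <- matrix(c(rd, nrow(real_signals) - rd,
                  sd_, nrow(sim_signals) - sd_), nrow = 2, byrow = TRUE)
  chisq_p <- tryCatch({
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate table")
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, error = function(e) stats::fisher.test(tab)$p.value)
  wil <- function(a, b)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  list(real_detected_fraction = rd / nrow(real_signals),
       sim_detected_fraction = sd_ / nrow(sim_signals),
       chisq_p = chisq_p,
       wilcox_n_samples_p = wil(real_signals$n_samples,
                                sim_signals$n_samples),
       wilcox_abundance_p = wil(real_signals$abundance,
                                sim_signals$abundance))
}
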