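# Self-contained synthetic fixtures: toy genome, layered annotations, an
# insertional screen with planted fitness effects, LTR-tagged read pairs
# with a truth SAM, and CAGE tag tables.
#
# The generator emulates the screen design the pipeline targets: a pool of
# unique lentiviral integration positions shared by all samples of a system
# (all samples derive from one transfected population), 3 control + 3
# treated biological replicates sequenced to a fixed read depth, and
# selection acting multiplicatively on the relative abundance of each
# integration through its element's fitness multiplier.

#' Synthetic screen configuration
#'
#' Defaults describe the study conditions the test-bed models: a 2 x 500 kb
#' toy genome, 10 protein-coding gene models carrying 20 planted essential
#' exons of 5 kb (fitness multiplier 0.05, i.e. 20-fold depletion upon
#' selection), 2 planted enriched elements (multiplier 5), 2,000 unique
#' integration positions sequenced at 10,000 read-level events per sample
#' (mean depth 5 per position, so a 5 kb element carries about 50 baseline
#' events), and 3 replicates per arm.
#'
#' @param genome_lengths named contig lengths.
#' @param n_genes protein-coding genes (split evenly across contigs).
#' @param essential_length planted essential exon length in bp.
#' @param enriched_per_contig planted enriched elements per contig.
#' @param enriched_length enriched element length in bp.
#' @param fitness_map named survival multipliers per element class.
#' @param n_positions unique integration positions in the pool.
#' @param n_events read-level events per sample.
#' @param replicates biological replicates per arm.
#' @param read_length read length for [emit_reads()].
#' @param error_rate per-base sequencing error rate for [emit_reads()].
#' @return list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(genome_lengths = c(chr1 = 500000,
                                                 chr2 = 500000),
                              n_genes = 10,
                              essential_length = 5000,
                              enriched_per_contig = 1,
                              enriched_length = 2000,
                              fitness_map = c(essential_exon = 0.05,
                                              enriched_element = 5,
                                              neutral = 1),
                              n_positions = 2000,
                              n_events = 10000,
                              replicates = 3,
                              read_length = 80,
                              error_rate = 0) {
  stopifnot(all(fitness_map > 0), n_positions > 0, n_events > 0,
            replicates >= 1, length(genome_lengths) >= 1)
  structure(list(genome_lengths = genome_lengths, n_genes = n_genes,
                 essential_length = essential_length,
                 enriched_per_contig = enriched_per_contig,
                 enriched_length = enriched_length,
                 fitness_map = fitness_map, n_positions = n_positions,
                 n_events = n_events, replicates = replicates,
                 read_length = read_length, error_rate = error_rate),
            class = "screen_sim_config")
}

#' Generate a random toy genome
#'
#' I.i.d. uniform A/C/G/T per base; deterministic under `seed`.
#'
#' @param config a [screen_sim_config()].
#' @param seed optional integer seed.
#' @return named character vector of sequences.
#' @export
generate_genome <- function(config = screen_sim_config(), seed = NULL) {
  draw <- function() {
    vapply(config$genome_lengths, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Fixed per-contig layout pitch (bp): gene i occupies
# [10k + (i-1)*55k, 10k + (i-1)*55k + 40k).
gene_layout <- function(contig_len, n_genes_contig) {
  needed <- 10000 + (n_genes_contig - 1) * 55000 + 40000 + 212000
  if (needed > contig_len)
    stopf("contig too short for %d genes (+ annotation zones): need %d bp",
          n_genes_contig, needed)
  10000 + (seq_len(n_genes_contig) - 1) * 55000
}

#' Generate the layered toy annotation with planted fitness elements
#'
#' Builds non-overlapping gene models (5 exons each; exons 2 and 4 are the
#' planted 5 kb essential exons), lncRNA genes, vlincRNAs, promoters,
#' enhancers, insulators, intronic and intergenic GENSCAN-only exons, a gene
#' desert zone at least 50 kb from every gene boundary, and the planted
#' enriched elements. The layout is deterministic given the configuration.
#'
#' @param config a [screen_sim_config()].
#' @return list: `genes`, `exons`, `sets` (hierarchy layers), `elements`
#'   (truth table: class, multiplier, expected direction), `tss`, and a
#'   ready [annotation_hierarchy()] as `hierarchy`.
#' @export
generate_annotations <- function(config = screen_sim_config()) {
  gl <- config$genome_lengths
  contigs <- names(gl)
  per_contig <- rep(config$n_genes %/% length(contigs), length(contigs))
  extra <- config$n_genes %% length(contigs)
  if (extra) per_contig[seq_len(extra)] <- per_contig[seq_len(extra)] + 1
  el <- config$essential_length
  if (el > 5000) stopf("essential_length > 5000 does not fit the exon slots")

  genes <- exons <- gsc <- prom <- list()
  for (ci in seq_along(contigs)) {
    ch <- contigs[ci]
    starts <- gene_layout(gl[[ci]], per_contig[ci])
    for (gi in seq_along(starts)) {
      s <- starts[gi]
      strand <- if (gi %% 2 == 1) "+" else "-"
      id <- sprintf("%s_g%d", ch, gi)
      genes[[id]] <- data.frame(gene_id = id, chrom = ch, start = s,
                                end = s + 40000, strand = strand,
                                type = "coding", stringsAsFactors = FALSE)
      off <- rbind(c(0, 1000), c(8000, 8000 + el), c(18000, 20000),
                   c(25000, 25000 + el), c(39000, 40000))
      exons[[id]] <- data.frame(gene_id = id, chrom = ch,
                                start = s + off[, 1], end = s + off[, 2],
                                strand = strand,
                                essential = c(FALSE, TRUE, FALSE, TRUE,
                                              FALSE),
                                stringsAsFactors = FALSE)
      gsc[[id]] <- gintervals(ch, s + 21000, s + 22000, strand)
      prom[[id]] <- if (strand == "+") gintervals(ch, s - 2000, s, strand)
                    else gintervals(ch, s + 40000, s + 42000, strand)
    }
    # lncRNA gene + annotation zones in [280k, 340k); desert beyond 338k+50k
    lid <- sprintf("%s_lnc1", ch)
    genes[[lid]] <- data.frame(gene_id = lid, chrom = ch, start = 280000,
                               end = 288000, strand = "+", type = "lncrna",
                               stringsAsFactors = FALSE)
    exons[[lid]] <- data.frame(gene_id = lid, chrom = ch,
                               start = c(280000, 286000),
                               end = c(281000, 288000), strand = "+",
                               essential = FALSE, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  rownames(genes) <- rownames(exons) <- NULL

  coding <- genes$type == "coding"
  sets <- list(
    exon_coding = {
      e <- exons[exons$gene_id %in% genes$gene_id[coding], ]
      gintervals(e$chrom, e$start, e$end, e$strand)
    },
    exon_lncrna = {
      e <- exons[exons$gene_id %in% genes$gene_id[!coding], ]
      gintervals(e$chrom, e$start, e$end, e$strand)
    },
    vlincrna = gintervals(contigs, 295000, 320000, "+"),
    promoter = do.call(rbind, prom),
    enhancer = gintervals(contigs, 325000, 326000),
    insulator = gintervals(contigs, 327000, 327500),
    genscan_exon = rbind(do.call(rbind, gsc),
                         gintervals(rep(contigs, each = 2),
                                    rep(c(350000, 420000), length(contigs)),
                                    rep(c(351000, 421000),
                                        length(contigs)))))

  ess <- exons[exons$essential, ]
  elements <- data.frame(chrom = ess$chrom, start = ess$start,
                         end = ess$end, class = "essential_exon",
                         stringsAsFactors = FALSE)
  if (config$enriched_per_contig > 0) {
    enr_starts <- 450000 + (seq_len(config$enriched_per_contig) - 1) * 10000
    elements <- rbind(elements, data.frame(
      chrom = rep(contigs, each = config$enriched_per_contig),
      start = rep(enr_starts, length(contigs)),
      end = rep(enr_starts + config$enriched_length, length(contigs)),
      class = "enriched_element", stringsAsFactors = FALSE))
  }
  elements$multiplier <- unname(config$fitness_map[elements$class])
  elements$expected_direction <- ifelse(elements$multiplier < 1, "depleted",
                                        ifelse(elements$multiplier > 1,
                                               "enriched", "none"))
  if (any(elements$end > gl[elements$chrom]))
    stopf("annotation layout exceeds contig bounds")

  tss <- data.frame(chrom = genes$chrom,
                    pos = ifelse(genes$strand == "+", genes$start,
                                 genes$end - 1),
                    strand = genes$strand, id = genes$gene_id,
                    type = genes$type, stringsAsFactors = FALSE)

  hierarchy <- annotation_hierarchy(sets, genes, exons,
                                    genome_lengths = gl)
  list(genes = genes, exons = exons, sets = sets, elements = elements,
       tss = tss, hierarchy = hierarchy)
}

#' Simulate the insertional screen
#'
#' A shared pool of unique integration positions is drawn uniformly over
#' the genome. Each control replicate resamples the configured read depth
#' multinomially with equal weights over the pool; each treated replicate
#' uses weights multiplied by the fitness multiplier of the element class
#' at each position (multinomial renormalization models relative-abundance
#' dynamics under selection at constant sequencing depth).
#'
#' @param config a [screen_sim_config()].
#' @param annotations output of [generate_annotations()].
#' @param seed optional integer seed.
#' @return list: `positions` (pool with class and multiplier), `counts`
#'   (positions x samples matrix), `matrix` (normalized
#'   `insertion_matrix`), `events` (named list of per-sample event
#'   data.frames, one row per read), `truth` (elements table).
#' @export
simulate_screen <- function(config = screen_sim_config(),
                            annotations = generate_annotations(config),
                            seed = NULL) {
  run <- function() {
    gl <- config$genome_lengths
    total <- sum(gl)
    u <- sort(sample.int(total, config$n_positions, replace = FALSE)) - 1
    offsets <- cumsum(c(0, unname(gl)))
    ci <- findInterval(u, offsets)
    positions <- data.frame(chrom = names(gl)[ci], pos = u - offsets[ci],
                            strand = sample(c("+", "-"),
                                            config$n_positions,
                                            replace = TRUE),
                            class = "neutral", stringsAsFactors = FALSE)
    ev <- annotations$elements
    for (k in seq_len(nrow(ev))) {
      hit <- positions$chrom == ev$chrom[k] & positions$pos >= ev$start[k] &
        positions$pos < ev$end[k]
      positions$class[hit] <- ev$class[k]
    }
    fm <- config$fitness_map
    positions$multiplier <- unname(fm[positions$class])
    if (anyNA(positions$multiplier))
      stopf("fitness_map lacks class '%s'",
            positions$class[is.na(positions$multiplier)][1])

    nrep <- config$replicates
    samples <- c(paste0("ctrl_", seq_len(nrep)),
                 paste0("trt_", seq_len(nrep)))
    counts <- sapply(seq_len(2 * nrep), function(j) {
      w <- if (j <= nrep) rep(1, config$n_positions)
           else positions$multiplier
      as.vector(stats::rmultinom(1, config$n_events, w))
    })
    colnames(counts) <- samples

    events <- lapply(stats::setNames(nm = samples), function(s) {
      idx <- rep(seq_len(config$n_positions), counts[, s])
      data.frame(chrom = positions$chrom[idx], pos = positions$pos[idx],
                 strand = positions$strand[idx], stringsAsFactors = FALSE)
    })
    keep <- rowSums(counts) > 0
    mat <- new_insertion_matrix(
      positions[keep, c("chrom", "pos", "strand")],
      counts[keep, , drop = FALSE],
      stats::setNames(rep(config$n_events, length(samples)), samples))
    list(positions = positions, counts = counts,
         matrix = normalize_depth(mat), events = events,
         truth = annotations$elements)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Emit LTR-tagged paired reads and a truth SAM for screen events
#'
#' Per event, read 2 is the LTR tag followed by `read_length` genomic bases
#' 3' of the insertion point on the event strand; read 1 is the opposing
#' genomic mate within the pair-span limit. The truth SAM holds the
#' tag-trimmed alignments, so the insertion caller can be exercised without
#' an external aligner: calling insertions from the truth SAM must return
#' the planted coordinates exactly.
#'
#' @param events data.frame with `chrom`, `pos`, `strand` (one row per
#'   read pair).
#' @param genome named character vector of contig sequences.
#' @param ltr_tag tag prepended to read 2; default [inset_ltr_tag()].
#' @param read_length genomic bases per mate; default 80.
#' @param error_rate per-base substitution rate on the genomic portions.
#' @param seed optional integer seed.
#' @return list: `pairs` (FASTQ-ready data.frame), `truth` (aligned-pair
#'   data.frame in [read_sam_pairs()] layout), `skipped` (events too close
#'   to a contig edge).
#' @export
emit_reads <- function(events, genome, ltr_tag = inset_ltr_tag(),
                       read_length = 80, error_rate = 0, seed = NULL) {
  run <- function() {
    L <- read_length
    clen <- nchar(genome)
    n <- nrow(events)
    if (n == 0)
      return(list(pairs = data.frame(id = character(), seq1 = character(),
                                     qual1 = character(),
                                     seq2 = character(),
                                     qual2 = character()),
                  truth = NULL, skipped = 0L))
    gap <- sample(20:200, n, replace = TRUE)
    p <- events$pos
    len <- clen[events$chrom]
    plus <- events$strand == "+"
    # genomic spans of read2 (tag-trimmed) and read1
    r2s <- ifelse(plus, p + 1, p - L)
    r1s <- ifelse(plus, p + 1 + L + gap, p - L - gap - L)
    ok <- ifelse(plus, r1s + L <= len, r1s >= 0) &
      r2s >= 0 & r2s + L <= len
    skipped <- sum(!ok)
    idx <- which(ok)
    if (!length(idx))
      return(list(pairs = data.frame(id = character(),
                                     seq1 = character(),
                                     qual1 = character(),
                                     seq2 = character(),
                                     qual2 = character()),
                  truth = NULL, skipped = skipped))

    fetch <- function(ch, s0, w)
      substr(genome[[ch]], s0 + 1, s0 + w)
    seq2g <- vapply(idx, function(i)
      fetch(events$chrom[i], r2s[i], L), character(1))
    seq1g <- vapply(idx, function(i)
      fetch(events$chrom[i], r1s[i], L), character(1))
    s2 <- ifelse(plus[idx], seq2g, revcomp(seq2g))
    s1 <- ifelse(plus[idx], revcomp(seq1g), seq1g)
    if (error_rate > 0) {
      s2 <- mutate_seq(s2, error_rate)
      s1 <- mutate_seq(s1, error_rate)
    }
    q <- strrep(rawToChar(as.raw(33 + 37)), L)
    id <- sprintf("ins_%06d", idx)
    pairs <- data.frame(id = id, seq1 = s1, qual1 = q,
                        seq2 = paste0(ltr_tag, s2),
                        qual2 = paste0(strrep(rawToChar(as.raw(33 + 37)),
                                              nchar(ltr_tag)), q),
                        stringsAsFactors = FALSE)
    truth <- rbind(
      data.frame(pair_id = id, mate = 1L, chrom = events$chrom[idx],
                 start = r1s[idx], end = r1s[idx] + L,
                 strand = ifelse(plus[idx], "-", "+"), mapq = 60,
                 mapped = TRUE, stringsAsFactors = FALSE),
      data.frame(pair_id = id, mate = 2L, chrom = events$chrom[idx],
                 start = r2s[idx], end = r2s[idx] + L,
                 strand = events$strand[idx], mapq = 60, mapped = TRUE,
                 stringsAsFactors = FALSE))
    list(pairs = pairs, truth = truth, skipped = skipped)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Random substitutions at the given per-base rate.
mutate_seq <- function(seqs, rate) {
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(b)) < rate
    if (any(hit))
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate per-sample CAGE tag tables
#'
#' Each sample carries Poisson-depth tags at the true TSS positions (same
#' strand) over a uniform background of single-depth tags at random
#' positions and strands.
#'
#' @param tss data.frame of true TSSs: `chrom`, `pos`, `strand`.
#' @param genome_lengths named contig lengths.
#' @param n_samples number of CAGE samples; default 6.
#' @param signal_mean mean tag depth at a true TSS; default 5.
#' @param background_tags background tag positions per sample; default 200.
#' @param seed optional integer seed.
#' @return list of [cage_sample()] objects.
#' @export
simulate_cage <- function(tss, genome_lengths, n_samples = 6,
                          signal_mean = 5, background_tags = 200,
                          seed = NULL) {
  run <- function() {
    lapply(seq_len(n_samples), function(si) {
      depth <- stats::rpois(nrow(tss), signal_mean)
      sig <- data.frame(chrom = tss$chrom, pos = tss$pos,
                        strand = tss$strand, depth = depth,
                        stringsAsFactors = FALSE)[depth > 0, , drop = FALSE]
      bg_pos <- simulate_random_insertions(background_tags, genome_lengths)
      bg <- data.frame(chrom = bg_pos$chrom, pos = bg_pos$pos,
                       strand = sample(c("+", "-"), background_tags,
                                       replace = TRUE),
                       depth = 1, stringsAsFactors = FALSE)
      cage_sample(sprintf("sample_%02d", si), rbind(sig, bg))
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
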