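# Region-level fitness calls: SICER-style enrichment/depletion islands per
# replicate, consensus clusters (CACFs) shared by >= 2 of 3 replicates, and
# the random-placement null used to validate the cluster caller.
#
# The island model follows the published SICER design: the genome is tiled
# in non-overlapping windows, each window is scored by an upper-tail Poisson
# probability of its treatment event count given the scaled control
# expectation (floored by the genome-wide mean), windows passing a lenient
# screen are aggregated into gap-tolerant islands, island significance comes
# from Fisher's combination of member-window probabilities, and islands are
# selected by BH FDR. Depleted islands are obtained by swapping the
# treatment and control roles.

#' Island-calling parameters
#'
#' @param window_size tiling window in bp; default 200.
#' @param gap_size maximum run of ineligible windows bridged inside one
#'   island, in bp; must be a multiple of `window_size`; default 600.
#' @param island_fdr BH FDR threshold on islands; default 0.01.
#' @param window_p window-level eligibility screen; default 0.2.
#' @return list of class `island_params`.
#' @export
island_params <- function(window_size = 200, gap_size = 600,
                          island_fdr = 0.01, window_p = 0.2) {
  stopifnot(window_size > 0, gap_size >= 0,
            gap_size %% window_size == 0,
            island_fdr > 0, island_fdr < 1)
  structure(list(window_size = window_size, gap_size = gap_size,
                 island_fdr = island_fdr, window_p = window_p),
            class = "island_params")
}

# Per-window event counts for one sample: named list chrom -> integer vector.
window_counts <- function(positions, genome_lengths, window_size) {
  lapply(stats::setNames(nm = names(genome_lengths)), function(ch) {
    nw <- ceiling(genome_lengths[[ch]] / window_size)
    p <- positions$pos[positions$chrom == ch]
    if (!length(p)) return(integer(nw))
    tabulate(pmin(floor(p / window_size) + 1L, nw), nbins = nw)
  })
}

#' Score genome windows for insertion enrichment
#'
#' Windows are scored with the upper-tail Poisson probability
#' `P(X >= k_treat)` at expectation `max(k_ctrl, lambda0) * N_treat/N_ctrl`,
#' where `lambda0` is the genome-wide mean control events per window.
#' `direction = "depleted"` swaps the roles of the two samples. Windows with
#' `p <= window_p` are eligible for island formation.
#'
#' @param treat_positions,control_positions data.frames of raw insertion
#'   events (`chrom`, `pos`; one row per read, not unique sites).
#' @param genome_lengths named numeric vector of contig lengths.
#' @param params an [island_params()] object.
#' @param direction `"enriched"` or `"depleted"`.
#' @return data.frame of windows holding at least one event of either
#'   sample: `chrom`, `window` (0-based index), `start`, `end`, `k_treat`,
#'   `k_ctrl`, `p`, `eligible`.
#' @export
score_windows <- function(treat_positions, control_positions, genome_lengths,
                          params = island_params(),
                          direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (direction == "depleted") {
    tmp <- treat_positions
    treat_positions <- control_positions
    control_positions <- tmp
  }
  ws <- params$window_size
  kt <- window_counts(treat_positions, genome_lengths, ws)
  kc <- window_counts(control_positions, genome_lengths, ws)
  n_treat <- sum(vapply(kt, sum, numeric(1)))
  n_ctrl <- sum(vapply(kc, sum, numeric(1)))
  if (n_treat + n_ctrl == 0)
    return(data.frame(chrom = character(), window = integer(),
                      start = numeric(), end = numeric(),
                      k_treat = integer(), k_ctrl = integer(),
                      p = numeric(), eligible = logical()))
  n_windows <- sum(vapply(kt, length, numeric(1)))
  lambda0 <- n_ctrl / n_windows
  ratio <- if (n_ctrl > 0) n_treat / n_ctrl else 1

  out <- lapply(names(kt), function(ch) {
    k_t <- kt[[ch]]; k_c <- kc[[ch]]
    idx <- which(k_t > 0 | k_c > 0)
    if (!length(idx)) return(NULL)
    expectation <- pmax(k_c[idx], lambda0) * ratio
    p <- stats::ppois(k_t[idx] - 1, expectation, lower.tail = FALSE)
    data.frame(chrom = ch, window = idx - 1L,
               start = (idx - 1) * ws,
               end = pmin(idx * ws, genome_lengths[[ch]]),
               k_treat = k_t[idx], k_ctrl = k_c[idx], p = p,
               eligible = p <= params$window_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(), window = integer(),
                      start = numeric(), end = numeric(),
                      k_treat = integer(), k_ctrl = integer(),
                      p = numeric(), eligible = logical())
  rownames(out) <- NULL
  out
}

#' Aggregate eligible windows into significant islands
#'
#' Islands are maximal runs of eligible windows in which consecutive
#' eligible windows are separated by at most `gap_size` bp of ineligible
#' windows. The island score is the sum of `-ln p` over member windows;
#' island significance is the chi-square upper tail of twice the score at
#' `2 x n_windows` degrees of freedom (Fisher's combination), BH-adjusted
#' across all islands. Islands with `q <= island_fdr` are emitted, trimmed
#' to the span from their first to last eligible window.
#'
#' @param windows scored windows from [score_windows()].
#' @param params an [island_params()] object.
#' @param direction direction label attached to emitted clusters.
#' @return data.frame of clusters: `chrom`, `start`, `end`, `direction`,
#'   `n_windows`, `score`, `k_treat`, `k_ctrl`, `p`, `q`.
#' @export
call_islands <- function(windows, params = island_params(),
                         direction = "enriched") {
  w <- windows[windows$eligible, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_windows = integer(), score = numeric(),
                      k_treat = numeric(), k_ctrl = numeric(),
                      p = numeric(), q = numeric())
  if (nrow(w) == 0) return(empty)
  w <- w[order(w$chrom, w$window), , drop = FALSE]
  max_gap_windows <- params$gap_size / params$window_size
  new_island <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                    (w$window[-1] - w$window[-nrow(w)] - 1) > max_gap_windows)
  island_id <- cumsum(new_island)

  agg <- function(f, col) as.vector(tapply(w[[col]], island_id, f))
  isl <- data.frame(
    chrom = as.vector(tapply(w$chrom, island_id, `[`, 1)),
    start = agg(min, "start"),
    end = agg(max, "end"),
    direction = direction,
    n_windows = as.vector(tapply(island_id, island_id, length)),
    score = as.vector(tapply(-log(w$p), island_id, sum)),
    k_treat = agg(sum, "k_treat"),
    k_ctrl = agg(sum, "k_ctrl"),
    stringsAsFactors = FALSE)
  isl$p <- stats::pchisq(2 * isl$score, df = 2 * isl$n_windows,
                         lower.tail = FALSE)
  isl$q <- bh_adjust(isl$p)
  out <- isl[isl$q <= params$island_fdr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call enriched and depleted insertion clusters for one replicate pair
#'
#' Runs [score_windows()] and [call_islands()] in both directions.
#'
#' @param treat_positions,control_positions raw insertion events.
#' @param genome_lengths named contig lengths.
#' @param params an [island_params()] object.
#' @return data.frame of clusters in both directions.
#' @export
call_fitness_clusters <- function(treat_positions, control_positions,
                                  genome_lengths, params = island_params()) {
  rbind(
    call_islands(score_windows(treat_positions, control_positions,
                               genome_lengths, params, "enriched"),
                 params, "enriched"),
    call_islands(score_windows(treat_positions, control_positions,
                               genome_lengths, params, "depleted"),
                 params, "depleted"))
}

#' Consensus clusters across biological replicates (CACFs)
#'
#' Same-direction clusters from different replicates are pooled and grouped
#' into connected components of pairwise overlap; a component supported by
#' at least `min_support` distinct replicates becomes a CACF whose interval
#' is the union of its member clusters. Opposite-direction clusters never
#' combine.
#'
#' @param cluster_sets list of per-replicate cluster data.frames (from
#'   [call_fitness_clusters()]); names are replicate ids.
#' @param min_support minimum number of distinct supporting replicates;
#'   default 2.
#' @return data.frame of CACFs: `chrom`, `start`, `end`, `direction`,
#'   `support` (comma-joined replicate ids), `n_support`.
#' @export
consensus_cacfs <- function(cluster_sets, min_support = 2) {
  if (is.null(names(cluster_sets)))
    names(cluster_sets) <- paste0("rep", seq_along(cluster_sets))
  pooled <- do.call(rbind, lapply(names(cluster_sets), function(id) {
    x <- cluster_sets[[id]]
    if (is.null(x) || nrow(x) == 0) return(NULL)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               direction = x$direction, replicate = id,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      support = character(), n_support = integer())
  if (is.null(pooled) || nrow(pooled) == 0) return(empty)

  out <- lapply(split(pooled, pooled$direction), function(d) {
    gr <- as_granges(d)
    comp <- GenomicRanges::reduce(gr, ignore.strand = TRUE,
                                  min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, comp, ignore.strand = TRUE,
                                       select = "first")
    support <- lapply(seq_along(comp), function(ci)
      sort(unique(d$replicate[hit == ci])))
    n_sup <- vapply(support, length, integer(1))
    keep <- which(n_sup >= min_support)
    if (!length(keep)) return(NULL)
    cd <- from_granges(comp[keep])
    data.frame(chrom = cd$chrom, start = cd$start, end = cd$end,
               direction = d$direction[1],
               support = vapply(support[keep], paste, "", collapse = ","),
               n_support = n_sup[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coordinate-merge CACFs across systems into unique regions
#'
#' Strand- and direction-agnostic merge of all CACF intervals; overlapping
#' calls from different systems collapse into one unique region.
#'
#' @param cacfs data.frame of CACFs (possibly from several systems).
#' @return list with `merged` (interval data.frame) and `n_unique`.
#' @export
merge_unique <- function(cacfs) {
  if (nrow(cacfs) == 0)
    return(list(merged = cacfs[, c("chrom", "start", "end")], n_unique = 0L))
  merged <- merge_intervals(data.frame(chrom = cacfs$chrom,
                                       start = cacfs$start,
                                       end = cacfs$end, strand = "*",
                                       stringsAsFactors = FALSE))
  list(merged = merged, n_unique = nrow(merged))
}

#' Uniform random insertion positions
#'
#' Draws `n` positions uniformly over the concatenated genome; reproducible
#' under `seed`.
#'
#' @param n number of positions.
#' @param genome_lengths named contig lengths.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return data.frame with `chrom`, `pos`.
#' @export
simulate_random_insertions <- function(n, genome_lengths, seed = NULL) {
  draw <- function() {
    if (n == 0)
      return(data.frame(chrom = character(), pos = numeric()))
    total <- sum(genome_lengths)
    u <- sample.int(total, n, replace = TRUE) - 1
    offsets <- cumsum(c(0, unname(genome_lengths)))
    i <- findInterval(u, offsets, rightmost.closed = FALSE)
    data.frame(chrom = names(genome_lengths)[i], pos = u - offsets[i],
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Random-placement null for the cluster/CACF pipeline
#'
#' For each simulation the same number of events per sample is re-drawn
#' uniformly over the genome and the full per-replicate cluster + CACF
#' pipeline is re-run; per-simulation ratios of simulated to real cluster
#' and CACF counts quantify how often random insertions produce calls.
#'
#' @param screen list with `control` and `treated`: each a list of 3
#'   per-replicate event data.frames (`chrom`, `pos`).
#' @param genome_lengths named contig lengths.
#' @param params an [island_params()] object.
#' @param n_simulations number of simulations; default 100.
#' @param seed optional integer seed.
#' @return list with `real` (cluster and CACF counts), `ratios` (data.frame
#'   per simulation) and `summary` (max/mean of each ratio).
#' @export
null_cluster_ratio <- function(screen, genome_lengths,
                               params = island_params(),
                               n_simulations = 100, seed = NULL) {
  run_once <- function(ctrl, trt) {
    clusters <- lapply(seq_along(trt), function(i)
      call_fitness_clusters(trt[[i]], ctrl[[i]], genome_lengths, params))
    names(clusters) <- paste0("rep", seq_along(clusters))
    cacfs <- consensus_cacfs(clusters)
    list(n_clusters = sum(vapply(clusters, nrow, integer(1))),
         n_cacfs = nrow(cacfs))
  }
  real <- run_once(screen$control, screen$treated)
  if (real$n_clusters == 0)
    stopf("no real clusters: null ratio undefined")
  n_events <- lapply(c(screen$control, screen$treated), nrow)

  sims <- function() {
    lapply(seq_len(n_simulations), function(s) {
      ev <- lapply(n_events, function(n)
        simulate_random_insertions(n, genome_lengths))
      nc <- length(screen$control)
      run_once(ev[seq_len(nc)], ev[nc + seq_along(screen$treated)])
    })
  }
  res <- if (is.null(seed)) sims() else withr::with_seed(seed, sims())
  ratios <- data.frame(
    sim = seq_len(n_simulations),
    cluster_ratio = vapply(res, function(r)
      r$n_clusters / real$n_clusters, numeric(1)),
    cacf_ratio = vapply(res, function(r) {
      if (real$n_cacfs == 0) NA_real_ else r$n_cacfs / real$n_cacfs
    }, numeric(1)))
  list(real = real, ratios = ratios,
       summary = list(max_cluster_ratio = max(ratios$cluster_ratio),
                      mean_cluster_ratio = mean(ratios$cluster_ratio),
                      max_cacf_ratio = suppressWarnings(max(ratios$cacf_ratio)),
                      mean_cacf_ratio = mean(ratios$cacf_ratio)))
}

#' Screen-level summary report
#'
#' Totals and the derived percentages used in reporting, each rounded
#' half-up to one decimal; percentages with zero denominators are `NA`.
#'
#' @param iacfs data.frame of IACF calls (`chrom`, `pos`; one row per call,
#'   calls from different systems counted independently).
#' @param cacfs data.frame of CACFs (one row per call across systems).
#' @param n_sites total number of tested insertion sites (the IACF testing
#'   universe summed over systems).
#' @return list of class `inset_summary` with `counts` and `percentages`.
#' @export
overlap_summary <- function(iacfs, cacfs, n_sites) {
  n_iacf <- nrow(iacfs)
  n_cacf <- nrow(cacfs)
  uniq_iacf <- if (n_iacf) nrow(unique(iacfs[, c("chrom", "pos")])) else 0L
  uniq_cacf <- merge_unique(cacfs)$n_unique

  if (n_iacf && n_cacf) {
    ipts <- gintervals(iacfs$chrom, iacfs$pos, iacfs$pos + 1)
    cint <- gintervals(cacfs$chrom, cacfs$start, cacfs$end)
    hits <- intersect_intervals(ipts, cint)
    iacf_in_cacf <- length(unique(hits$query))
    cacf_no_iacf <- n_cacf - length(unique(hits$subject))
  } else {
    iacf_in_cacf <- 0L
    cacf_no_iacf <- n_cacf
  }
  counts <- list(sites_tested = n_sites, iacfs = n_iacf,
                 unique_iacfs = uniq_iacf, cacfs = n_cacf,
                 unique_merged_cacfs = uniq_cacf,
                 iacfs_inside_cacfs = iacf_in_cacf,
                 cacfs_without_iacfs = cacf_no_iacf)
  percentages <- list(
    pct_iacf_of_sites = pct_of(n_iacf, n_sites),
    pct_unique_iacfs = pct_of(uniq_iacf, n_iacf),
    pct_iacfs_inside_cacfs = pct_of(iacf_in_cacf, n_iacf),
    pct_cacfs_without_iacfs = pct_of(cacf_no_iacf, n_cacf),
    pct_unique_merged_cacfs = pct_of(uniq_cacf, n_cacf))
  structure(list(counts = counts, percentages = percentages),
            class = "inset_summary")
}

#' @export
print.inset_summary <- function(x, ...) {
  cat("Screen summary\n counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %s\n", nm, format(x$counts[[nm]])))
  cat(" percentages:\n")
  for (nm in names(x$percentages))
    cat(sprintf("  %-26s %s\n", nm, format(x$percentages[[nm]])))
  invisible(x)
}
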