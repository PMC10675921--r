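# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# O(n*m) all-pairs interval overlap (>= 1 shared base; optional strand).
brute_overlaps <- function(query, subject, strand_aware = FALSE) {
  out <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      if (!(query$start[i] < subject$end[j] &&
            subject$start[j] < query$end[i])) next
      if (strand_aware) {
        qs <- query$strand[i]; ss <- subject$strand[j]
        if (qs %in% c("+", "-") && ss %in% c("+", "-") && qs != ss) next
      }
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer()))
  m <- do.call(rbind, out)
  d <- data.frame(query = m[, 1], subject = m[, 2])
  d[order(d$query, subject$start[d$subject], d$subject), , drop = FALSE]
}

# Textbook step-up BH definition: q_i = min over p_(j) >= p_(i) of
# p_(j) * m / rank(j), clipped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ranks_ge <- which(p[ord] >= p[i])
    q[i] <- min(1, min(p[ord][ranks_ge] * m / ranks_ge))
  }
  q
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
brute_wilcox <- function(a, b) {
  v <- c(a, b)
  n <- length(v); na <- length(a)
  w_obs <- sum(rank(v)[seq_len(na)])
  combs <- utils::combn(n, na)
  w_all <- apply(combs, 2, function(idx) sum(rank(v)[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exhaustive SICER-style island caller: direct loops over every window.
brute_islands <- function(treat, ctrl, genome_lengths, params,
                          direction = "enriched") {
  if (direction == "depleted") { tmp <- treat; treat <- ctrl; ctrl <- tmp }
  ws <- params$window_size
  win <- list()
  n_windows <- 0
  for (ch in names(genome_lengths)) {
    nw <- ceiling(genome_lengths[[ch]] / ws)
    n_windows <- n_windows + nw
    kt <- kc <- integer(nw)
    for (p in treat$pos[treat$chrom == ch]) {
      w <- min(floor(p / ws) + 1, nw); kt[w] <- kt[w] + 1L
    }
    for (p in ctrl$pos[ctrl$chrom == ch]) {
      w <- min(floor(p / ws) + 1, nw); kc[w] <- kc[w] + 1L
    }
    win[[ch]] <- list(kt = kt, kc = kc)
  }
  n_t <- sum(sapply(win, function(x) sum(x$kt)))
  n_c <- sum(sapply(win, function(x) sum(x$kc)))
  lambda0 <- n_c / n_windows
  ratio <- if (n_c > 0) n_t / n_c else 1
  islands <- list()
  for (ch in names(win)) {
    kt <- win[[ch]]$kt; kc <- win[[ch]]$kc
    p <- ppois(kt - 1, pmax(kc, lambda0) * ratio, lower.tail = FALSE)
    elig <- which(p <= params$window_p)
    if (!length(elig)) next
    cur <- list(first = elig[1], last = elig[1], score = -log(p[elig[1]]),
                k = 1L)
    flush <- function(cur) {
      islands[[length(islands) + 1]] <<- data.frame(
        chrom = ch, start = (cur$first - 1) * ws,
        end = min(cur$last * ws, genome_lengths[[ch]]),
        n_windows = cur$k, score = cur$score)
    }
    for (w in elig[-1]) {
      if ((w - cur$last - 1) * ws <= params$gap_size) {
        cur$last <- w; cur$score <- cur$score - log(p[w]); cur$k <- cur$k + 1L
      } else { flush(cur); cur <- list(first = w, last = w,
                                       score = -log(p[w]), k = 1L) }
    }
    flush(cur)
  }
  if (!length(islands))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      score = numeric(), p = numeric(), q = numeric()))
  isl <- do.call(rbind, islands)
  isl$p <- pchisq(2 * isl$score, 2 * isl$n_windows, lower.tail = FALSE)
  isl$q <- brute_bh(isl$p)
  isl <- isl[isl$q <= params$island_fdr, , drop = FALSE]
  rownames(isl) <- NULL
  isl
}

# Random interval set on a toy genome.
random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 1000,
                            max_len = 60, stranded = TRUE) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             strand = if (stranded) sample(c("+", "-", "*"), n, TRUE)
                      else "*",
             stringsAsFactors = FALSE)
}

# Insertion matrix built directly from a counts matrix.
matrix_from_counts <- function(counts, lib_sizes,
                               chrom = "c1",
                               pos = seq_len(nrow(counts)) * 10) {
  sites <- data.frame(chrom = chrom, pos = pos, strand = "*",
                      stringsAsFactors = FALSE)
  m <- structure(list(sites = sites, counts = counts,
                      lib_sizes = lib_sizes, norm = NULL),
                 class = "insertion_matrix")
  normalize_depth(m)
}

phred_string <- function(q, n) strrep(rawToChar(as.raw(33 + q)), n)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
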