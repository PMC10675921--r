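# SICER-style window scoring, island calling, CACF consensus, null
# simulation and the summary report.

gl1 <- c(c1 = 100000)

test_that("score_windows computes the Poisson tail with the lambda0 floor", {
  none <- score_windows(data.frame(chrom = character(), pos = numeric()),
                        data.frame(chrom = character(), pos = numeric()),
                        gl1)
  expect_equal(nrow(none), 0)

  # 30 treatment events in one window over a sparse control background
  treat <- data.frame(chrom = "c1", pos = c(rep(450, 30), 90000))
  ctrl <- data.frame(chrom = "c1", pos = seq(0, 99800, by = 200) + 1)
  sw <- score_windows(treat, ctrl, gl1, island_params())
  hot <- sw[sw$window == 2, ]  # window [400, 600)
  expect_equal(hot$k_treat, 30)
  # expectation = max(k_ctrl, lambda0) * N_t/N_c with k_ctrl = 1, lambda0 = 1
  lambda <- 1 * (nrow(treat) / nrow(ctrl))
  expect_equal(hot$p, ppois(29, lambda, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(hot$p, 1e-20)
  expect_true(hot$eligible)

  # proportional samples: window p is not extreme, mostly ineligible
  withr::local_seed(13)
  prop_t <- simulate_random_insertions(2000, gl1)
  prop_c <- simulate_random_insertions(2000, gl1)
  swp <- score_windows(prop_t, prop_c, gl1)
  expect_lt(mean(swp$eligible), 0.35)
})

test_that("single strong window forms an island whose p equals the window p", {
  w <- data.frame(chrom = "c1", window = 10L, start = 2000, end = 2200,
                  k_treat = 30L, k_ctrl = 1L, p = 1e-6, eligible = TRUE)
  isl <- call_islands(w, island_params())
  expect_equal(nrow(isl), 1)
  # Fisher combination with k = 1 reduces to the window p
  expect_equal(isl$p, 1e-6, tolerance = 1e-9)
  expect_equal(isl$q, 1e-6, tolerance = 1e-9)
})

test_that("islands split on gaps larger than gap_size", {
  w <- data.frame(chrom = "c1", window = c(10L, 13L, 20L),
                  start = c(2000, 2600, 4000), end = c(2200, 2800, 4200),
                  k_treat = 30L, k_ctrl = 1L, p = 1e-8, eligible = TRUE)
  isl <- call_islands(w, island_params(gap_size = 600))
  # windows 10 and 13 bridge (gap 2 windows = 400 bp); window 20 is separate
  expect_equal(nrow(isl), 2)
  expect_equal(isl$n_windows, c(2L, 1L))
  expect_equal(isl$start, c(2000, 4000))
  expect_equal(isl$end, c(2800, 4200))
})

test_that("planted dense region yields exactly one enriched island at its span", {
  withr::local_seed(31)
  ctrl <- simulate_random_insertions(200, gl1)
  treat <- rbind(simulate_random_insertions(200, gl1),
                 data.frame(chrom = "c1",
                            pos = sample(50000:51999, 100, replace = TRUE)))
  sw <- score_windows(treat, ctrl, gl1)
  isl <- call_islands(sw)
  expect_equal(nrow(isl), 1)
  ws <- island_params()$window_size
  expect_lte(abs(isl$start - 50000), ws)
  expect_lte(abs(isl$end - 52000), ws)
})

test_that("island caller agrees with the exhaustive window-scan oracle", {
  withr::local_seed(47)
  gl <- c(c1 = 60000, c2 = 40000)
  params <- island_params()
  for (rep in 1:6) {
    ctrl <- simulate_random_insertions(800, gl)
    treat <- simulate_random_insertions(800, gl)
    # plant a couple of dense patches so some islands exist
    treat <- rbind(treat, data.frame(
      chrom = sample(names(gl), 60, replace = TRUE),
      pos = sample(10000:12000, 60, replace = TRUE)))
    for (dir in c("enriched", "depleted")) {
      got <- call_islands(score_windows(treat, ctrl, gl, params, dir),
                          params, dir)
      exp <- brute_islands(treat, ctrl, gl, params, dir)
      expect_equal(nrow(got), nrow(exp))
      if (nrow(exp)) {
        expect_equal(got$start, exp$start)
        expect_equal(got$end, exp$end)
        expect_equal(got$score, exp$score, tolerance = 1e-9)
        expect_equal(got$q, exp$q, tolerance = 1e-9)
      }
    }
  }
})

test_that("swapping samples swaps enriched and depleted labels", {
  withr::local_seed(61)
  gl <- c(c1 = 60000)
  a <- rbind(simulate_random_insertions(500, gl),
             data.frame(chrom = "c1", pos = sample(20000:21999, 80, TRUE)))
  b <- simulate_random_insertions(500, gl)
  fwd <- call_fitness_clusters(a, b, gl)
  rev <- call_fitness_clusters(b, a, gl)
  fwd_enr <- fwd[fwd$direction == "enriched", c("chrom", "start", "end")]
  rev_dep <- rev[rev$direction == "depleted", c("chrom", "start", "end")]
  expect_equal(fwd_enr, rev_dep, ignore_attr = TRUE)
})

test_that("consensus requires >=2 same-direction replicates; union interval", {
  cl <- function(start, end, dir = "enriched")
    data.frame(chrom = "c1", start = start, end = end, direction = dir)

  expect_equal(nrow(consensus_cacfs(list(r1 = cl(100, 300), r2 = cl(1, 2)[0, ],
                                         r3 = cl(1, 2)[0, ]))), 0)

  two <- consensus_cacfs(list(r1 = cl(100, 300), r2 = cl(250, 500),
                              r3 = cl(1, 2)[0, ]))
  expect_equal(nrow(two), 1)
  expect_equal(two$start, 100)
  expect_equal(two$end, 500)
  expect_equal(two$support, "r1,r2")
  expect_equal(two$n_support, 2L)

  opposite <- consensus_cacfs(list(r1 = cl(100, 300),
                                   r2 = cl(250, 500, "depleted"),
                                   r3 = cl(1, 2)[0, ]))
  expect_equal(nrow(opposite), 0)

  # every emitted CACF is covered by >= 2 replicate clusters of its direction
  withr::local_seed(71)
  sets <- lapply(1:3, function(i) {
    x <- random_intervals(30, chroms = "c1", max_pos = 5000, max_len = 300)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               direction = sample(c("enriched", "depleted"), 30, TRUE))
  })
  names(sets) <- paste0("r", 1:3)
  cacfs <- consensus_cacfs(sets)
  for (i in seq_len(nrow(cacfs))) {
    sup <- strsplit(cacfs$support[i], ",")[[1]]
    expect_gte(length(sup), 2)
    for (s in sup) {
      d <- sets[[s]]
      expect_true(any(d$direction == cacfs$direction[i] &
                        d$start < cacfs$end[i] & cacfs$start[i] < d$end))
    }
  }
})

test_that("merge_unique collapses coordinate-overlapping CACFs", {
  cac <- data.frame(chrom = "c1", start = c(0, 0, 40, 5, 14),
                    end = c(10, 10, 50, 15, 20),
                    direction = "enriched")
  expect_equal(merge_unique(cac[1:2, ])$n_unique, 1)
  expect_equal(merge_unique(cac[c(1, 3), ])$n_unique, 2)
  expect_equal(merge_unique(cac[c(1, 4, 5), ])$n_unique, 1)
})

test_that("simulate_random_insertions is seeded and uniform", {
  gl <- c(c1 = 600000, c2 = 400000)
  expect_equal(nrow(simulate_random_insertions(0, gl)), 0)
  a <- simulate_random_insertions(10000, gl, seed = 5)
  b <- simulate_random_insertions(10000, gl, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$pos >= 0))
  expect_true(all(a$pos < gl[a$chrom]))

  # chi-square goodness of fit over 10 equal bins of the concatenation
  offs <- c(c1 = 0, c2 = 600000)
  lin <- a$pos + offs[a$chrom]
  counts <- table(cut(lin, seq(0, 1e6, length.out = 11)))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("null_cluster_ratio reruns the pipeline on uniform redraws", {
  withr::local_seed(81)
  gl <- c(c1 = 80000)
  mk <- function(extra = NULL)
    rbind(simulate_random_insertions(600, gl), extra)
  dense <- function() data.frame(chrom = "c1",
                                 pos = sample(30000:32999, 120, TRUE))
  screen <- list(control = lapply(1:3, function(i) mk()),
                 treated = lapply(1:3, function(i) mk(dense())))
  nr <- null_cluster_ratio(screen, gl, island_params(),
                           n_simulations = 3, seed = 17)
  expect_gt(nr$real$n_clusters, 0)
  expect_gt(nr$real$n_cacfs, 0)
  expect_equal(nrow(nr$ratios), 3)
  nr2 <- null_cluster_ratio(screen, gl, island_params(),
                            n_simulations = 3, seed = 17)
  expect_identical(nr$ratios, nr2$ratios)
  expect_lte(nr$summary$mean_cacf_ratio, 0.05)
})

test_that("overlap_summary computes printed-style counts and percentages", {
  iacfs <- data.frame(chrom = "c1", pos = c(10, 10, 50, 120, 300))
  cacfs <- data.frame(chrom = "c1", start = c(0, 100, 100, 1000),
                      end = c(60, 200, 150, 1100),
                      direction = "depleted")
  s <- overlap_summary(iacfs, cacfs, n_sites = 1000)
  expect_equal(s$counts$iacfs, 5)
  expect_equal(s$counts$unique_iacfs, 4)
  expect_equal(s$counts$iacfs_inside_cacfs, 4)    # 10,10,50 in [0,60); 120
  expect_equal(s$counts$cacfs_without_iacfs, 1)
  expect_equal(s$counts$unique_merged_cacfs, 3)
  expect_equal(s$percentages$pct_iacf_of_sites, 0.5)
  expect_equal(s$percentages$pct_iacfs_inside_cacfs, 80.0)
  expect_equal(s$percentages$pct_cacfs_without_iacfs, 25.0)
  expect_equal(s$percentages$pct_unique_merged_cacfs, 75.0)

  none <- overlap_summary(iacfs, cacfs[0, ], n_sites = 1000)
  expect_true(is.na(none$percentages$pct_cacfs_without_iacfs))
})

test_that("percentage rounding is half-up at one decimal", {
  expect_equal(round_half_up(95.25, 1), 95.3)
  expect_equal(round_half_up(0.84999, 1), 0.8)
  expect_equal(round_half_up(4.16, 1), 4.2)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})
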