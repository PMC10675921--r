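# TSS windows, cluster categorization, composition-matched shuffling, CAGE
# signal and real-vs-simulated comparison.

cage_genes <- function() {
  list(genes = gintervals("c1", c(10000, 60000), c(40000, 90000),
                          c("+", "-")),
       exons = gintervals("c1", c(10000, 30000, 85000),
                          c(12000, 32000, 90000), c("+", "+", "-")))
}

test_that("TSS windows are 21 bp, strand-aware, with annotated exclusion", {
  w <- make_tss_windows(data.frame(chrom = "c1", pos = 1000, strand = "+"))
  expect_equal(w$start, 990)
  expect_equal(w$end, 1011)
  expect_equal(w$end - w$start, 21)

  ann <- data.frame(chrom = "c1", pos = 1007, strand = "+")
  expect_equal(nrow(make_tss_windows(
    data.frame(chrom = "c1", pos = 1000, strand = "+"),
    annotated_tss = ann)), 0)
  # same offset, opposite strand: kept
  ann_minus <- data.frame(chrom = "c1", pos = 1007, strand = "-")
  expect_equal(nrow(make_tss_windows(
    data.frame(chrom = "c1", pos = 1000, strand = "+"),
    annotated_tss = ann_minus)), 1)
  # contig-edge windows are clipped and flagged
  edge <- make_tss_windows(data.frame(chrom = "c1", pos = 4,
                                      strand = "+"))
  expect_equal(edge$start, 0)
  expect_true(edge$truncated)
})

test_that("window clustering merges per strand and categorizes by hierarchy", {
  g <- cage_genes()
  tss <- data.frame(chrom = "c1",
                    pos = c(11000, 11010,   # same-strand overlap in exon
                            20000,          # intron of + gene
                            70000,          # antisense within - gene
                            50000),         # intergenic
                    strand = c("+", "+", "+", "+", "+"))
  cl <- cluster_tss_windows(make_tss_windows(tss), g$exons, g$genes)
  expect_equal(nrow(cl), 4)
  expect_equal(sort(cl$category),
               sort(c("exon", "intron", "antisense_intragenic",
                      "intergenic")))

  both <- data.frame(chrom = "c1", pos = c(1000, 1000),
                     strand = c("+", "-"))
  expect_equal(nrow(cluster_tss_windows(make_tss_windows(both),
                                        g$exons, g$genes)), 2)

  # overlapping a sense exon and an intron: exon wins
  span <- data.frame(chrom = "c1", pos = 31995, strand = "+")
  cls <- cluster_tss_windows(make_tss_windows(span), g$exons, g$genes)
  expect_equal(cls$category, "exon")
})

test_that("shuffle_matched preserves composition and widths exactly", {
  g <- cage_genes()
  regions <- list(exon = g$exons, intron = gintervals("c1", 12000, 30000),
                  antisense_intragenic = gintervals("c1", 60000, 85000),
                  intergenic = gintervals("c1", 40000, 60000))
  tss <- data.frame(chrom = "c1",
                    pos = c(11000, 20000, 70000, 50000, 50500, 41000),
                    strand = "+")
  cl <- cluster_tss_windows(make_tss_windows(tss), g$exons, g$genes)
  sim <- shuffle_matched(cl, regions, factor = 20, seed = 3)
  expect_equal(nrow(sim), 20 * nrow(cl))
  expect_equal(as.list(table(sim$category)),
               lapply(as.list(table(cl$category)), function(x) 20 * x))
  expect_true(all((sim$end - sim$start) ==
                    (cl$end - cl$start)[sim$source]))
  # placements stay within their category's region space
  for (i in seq_len(nrow(sim))) {
    sp <- regions[[sim$category[i]]]
    expect_true(any(sp$start <= sim$start[i] & sim$end[i] <= sp$end))
  }
  sim2 <- shuffle_matched(cl, regions, factor = 20, seed = 3)
  expect_identical(sim, sim2)
  expect_error(shuffle_matched(cl, regions["exon"], factor = 2),
               "placement space")
})

test_that("normalized abundance is C x 1e7 / T", {
  expect_equal(normalized_cage_abundance(0, 1e7), 0)
  expect_equal(normalized_cage_abundance(5, 1e7), 5)
  expect_equal(normalized_cage_abundance(3, 2e6), 15)
  expect_error(normalized_cage_abundance(3, 0), "positive")
})

test_that("cluster_signal is strand-specific and linear in depth", {
  clusters <- gintervals("c1", c(100, 500), c(121, 521), c("+", "+"))
  s1 <- cage_sample("s1", data.frame(chrom = "c1", pos = c(110, 115, 510),
                                     strand = c("+", "+", "-"),
                                     depth = c(2, 3, 9)), total = 1e7)
  sig <- cluster_signal(clusters, list(s1))
  expect_equal(sig$n_samples, c(1, 0))
  expect_equal(sig$abundance, c(5, 0))

  # splitting one sample's tags into two records changes nothing
  s1b <- cage_sample("s1", data.frame(chrom = "c1",
                                      pos = c(110, 115, 115, 510),
                                      strand = c("+", "+", "+", "-"),
                                      depth = c(2, 1, 2, 9)), total = 1e7)
  expect_equal(cluster_signal(clusters, list(s1b))$abundance,
               sig$abundance)

  none <- cluster_signal(clusters,
                         list(cage_sample("x", data.frame(
                           chrom = "c1", pos = 9000, strand = "+",
                           depth = 4))))
  expect_equal(none$n_samples, c(0, 0))
  expect_equal(none$abundance, c(0, 0))
})

test_that("real vs simulated comparison uses chi-square and rank-sum", {
  same <- data.frame(cluster = 1:20, n_samples = rep(c(0, 2), 10),
                     abundance = rep(c(0, 5), 10))
  res <- compare_real_vs_sim(same, same)
  expect_gt(res$wilcox_n_samples_p, 0.9)

  real <- data.frame(cluster = 1:50, n_samples = 3, abundance = 9)
  sim <- data.frame(cluster = 1:50, n_samples = 0, abundance = 0)
  res2 <- compare_real_vs_sim(real, sim)
  expect_equal(res2$real_detected_fraction, 1)
  expect_equal(res2$sim_detected_fraction, 0)
  expect_lt(res2$chisq_p, 1e-4)

  # rank-sum p against the exact enumeration oracle
  ra <- data.frame(cluster = 1:3, n_samples = 1:3, abundance = 1:3)
  rb <- data.frame(cluster = 1:3, n_samples = 4:6, abundance = 4:6)
  res3 <- compare_real_vs_sim(ra, rb)
  expect_equal(res3$wilcox_n_samples_p, brute_wilcox(1:3, 4:6),
               tolerance = 1e-9)
  expect_equal(res3$wilcox_n_samples_p, 0.1, tolerance = 1e-9)
})

test_that("planted CAGE signal separates real from shuffled clusters", {
  withr::local_seed(12)
  gl <- c(c1 = 200000)
  true_tss <- data.frame(chrom = "c1",
                         pos = sort(sample(seq(1000, 199000, by = 50),
                                           120)),
                         strand = sample(c("+", "-"), 120, replace = TRUE))
  samples <- simulate_cage(true_tss, gl, n_samples = 8, signal_mean = 5,
                           background_tags = 200, seed = 99)
  wins <- make_tss_windows(true_tss)
  clusters <- cluster_tss_windows(wins, gintervals(character(), numeric(),
                                                   numeric()),
                                  gintervals(character(), numeric(),
                                             numeric()))
  expect_true(all(clusters$category == "intergenic"))
  sim <- shuffle_matched(clusters,
                         list(intergenic = gintervals("c1", 0, 200000)),
                         factor = 5, seed = 4)
  real_sig <- cluster_signal(clusters, samples)
  sim_sig <- cluster_signal(sim, samples)
  res <- compare_real_vs_sim(real_sig, sim_sig)
  expect_gt(res$real_detected_fraction, res$sim_detected_fraction)
  expect_lt(res$chisq_p, 0.01)
  expect_lt(res$wilcox_n_samples_p, 0.01)
  expect_lt(res$wilcox_abundance_p, 0.01)
})
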