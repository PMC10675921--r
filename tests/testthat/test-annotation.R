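# Hierarchical category assignment, element metrics, odds ratios,
# conservation extraction.

# Compact hand-built annotation: one 40 kb + gene with promoter/enhancer
# overlap cases, on a 500 kb contig.
toy_hierarchy <- function() {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(100000, 200000), end = c(140000, 240000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("g1", "g1", "g2", "g2"), chrom = "c1",
                      start = c(100000, 120000, 230000, 200000),
                      end = c(101000, 125000, 240000, 201000),
                      strand = c("+", "+", "-", "-"),
                      stringsAsFactors = FALSE)
  sets <- list(
    exon_coding = gintervals("c1", c(100000, 120000, 230000, 200000),
                             c(101000, 125000, 240000, 201000)),
    exon_lncrna = gintervals("c1", 300000, 302000),
    vlincrna = gintervals("c1", 310000, 330000),
    promoter = gintervals("c1", 98000, 100000),
    enhancer = gintervals("c1", c(124000, 340000), c(126000, 341000)),
    insulator = gintervals("c1", 342000, 342500),
    genscan_exon = gintervals("c1", c(110000, 400000),
                              c(111000, 401000)))
  annotation_hierarchy(sets, genes, exons,
                       genome_lengths = c(c1 = 500000))
}

test_that("hierarchy order resolves multi-category positions", {
  h <- toy_hierarchy()
  at <- function(pos) assign_category(data.frame(chrom = "c1", pos = pos), h)
  # inside both a coding exon and an enhancer -> exon wins
  expect_equal(at(124500), "EXON_CODING")
  expect_equal(at(300500), "EXON_LNCRNA")
  expect_equal(at(315000), "VLINCRNA")
  expect_equal(at(99000), "PROMOTER")
  expect_equal(at(340500), "ENHANCER")
  expect_equal(at(342100), "INSULATOR")
  # intronic GENSCAN-only exon >= 10 kb from the TSS
  expect_equal(at(110500), "GENSCAN_INTRONIC")
  expect_equal(at(400500), "GENSCAN_INTERGENIC")
  expect_equal(at(115000), "INTRON_OTHER")
  # 60 kb from the nearest gene boundary
  expect_equal(at(400500 - 500 + 99500), "GENE_DESERT")  # pos 499500
  expect_equal(at(150000), "INTERGENIC_OTHER")
  expect_error(at_err <- assign_category(
    data.frame(chrom = "cX", pos = 1), h), "unknown contig")
})

test_that("category assignment partitions all features exactly once", {
  h <- toy_hierarchy()
  withr::local_seed(8)
  pos <- data.frame(chrom = "c1",
                    pos = sample.int(500000, 400) - 1)
  cats <- assign_category(pos, h)
  expect_equal(length(cats), 400)
  expect_false(any(is.na(cats)))
  expect_true(all(cats %in% annotation_categories()))
  expect_equal(sum(table(cats)), 400)
})

test_that("disjoint categories are order-insensitive", {
  h <- toy_hierarchy()
  # vlincrna and insulator sets are disjoint: swapping their rank changes
  # nothing
  ord2 <- annotation_categories()
  i <- match(c("VLINCRNA", "INSULATOR"), ord2)
  ord2[i] <- ord2[rev(i)]
  h2 <- h; h2$order <- ord2
  withr::local_seed(9)
  pos <- data.frame(chrom = "c1", pos = sample.int(500000, 300) - 1)
  expect_equal(assign_category(pos, h), assign_category(pos, h2))
})

test_that("TSS distance bins are strand-aware with exon exclusion", {
  h <- toy_hierarchy()
  bin_at <- function(pos)
    tss_distance_bin(data.frame(chrom = "c1", pos = pos), h)
  expect_equal(bin_at(97000), "TSS_UP_0_5K")     # 3 kb 5' of g1 (+)
  expect_equal(bin_at(92000), "TSS_UP_5_10K")
  expect_equal(bin_at(108000), "TSS_DOWN_5_10K")
  expect_true(is.na(bin_at(85000)))              # 15 kb away
  # 2 kb downstream of g2 TSS (at 239999, '-' strand) but inside its exon
  expect_true(is.na(bin_at(238000)))
  # downstream of g2 past its first exon, at the outer bin edge
  expect_equal(bin_at(229999), "TSS_DOWN_5_10K")
  expect_true(is.na(bin_at(228000)))             # 11,999 bp: outside bins
})

test_that("density and depth follow the outlier rule", {
  counts <- cbind(s1 = c(5, 10000, 3, 0, 8))
  m <- matrix_from_counts(counts, lib_sizes = c(s1 = 1e5),
                          pos = c(100, 200, 300, 400, 5e6))
  elements <- gintervals("c1", 0, 2e6)
  dd <- density_and_depth(m, elements)
  # positions 100,200,300 overlap (400 has zero count is excluded? count 0)
  expect_equal(dd$n_positions, 3)
  expect_equal(dd$density_per_mb, 3 / 2)
  expect_equal(dd$avg_depth, mean(c(5, 3)))  # 10000 removed as outlier

  ten <- matrix_from_counts(cbind(s1 = rep(1, 10)),
                            lib_sizes = c(s1 = 1e5),
                            pos = seq(10, 100, by = 10))
  expect_equal(density_and_depth(ten, elements)$density_per_mb, 5)

  outside <- density_and_depth(m, gintervals("c1", 3e6, 4e6))
  expect_equal(outside$density_per_mb, 0)
  expect_true(is.na(outside$avg_depth))
  expect_error(density_and_depth(m, elements[0, ]), "empty")
})

test_that("density is invariant to splitting elements into abutting pieces", {
  withr::local_seed(19)
  m <- matrix_from_counts(cbind(s1 = rpois(50, 6) + 1),
                          lib_sizes = c(s1 = 1e5),
                          pos = sample.int(10000, 50))
  whole <- gintervals("c1", 0, 10000)
  pieces <- gintervals("c1", seq(0, 9000, 1000), seq(1000, 10000, 1000))
  expect_equal(density_and_depth(m, whole), density_and_depth(m, pieces))
})

test_that("odds ratios match the cross-product with Haldane fallback", {
  elem <- gintervals("c1", 0, 1000)
  mk <- function(n_in, n_out)
    data.frame(chrom = "c1", pos = c(seq_len(n_in) + 10,
                                     seq_len(n_out) + 5000))
  or <- odds_ratio(mk(10, 90), mk(5, 195), elem, haldane = FALSE)
  expect_equal(or$or, (10 / 90) / (5 / 195), tolerance = 1e-12)
  expect_equal(or$or, 4.3333, tolerance = 1e-4)

  ident <- odds_ratio(mk(10, 90), mk(20, 180), elem, haldane = FALSE)
  expect_equal(ident$or, 1)

  h <- odds_ratio(mk(0, 100), mk(5, 195), elem, haldane = TRUE)
  expect_true(is.finite(h$or))
  expect_equal(h$or, (0.5 / 100.5) / (5.5 / 195.5), tolerance = 1e-12)
  noh <- odds_ratio(mk(0, 100), mk(5, 195), elem, haldane = FALSE)
  expect_true(is.na(noh$or))

  # reciprocal property without zero cells
  a <- odds_ratio(mk(10, 90), mk(5, 195), elem, haldane = FALSE)$or
  b <- odds_ratio(mk(5, 195), mk(10, 90), elem, haldane = FALSE)$or
  expect_equal(a * b, 1, tolerance = 1e-12)
})

test_that("conservation scores average the two flanking bases", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("c1\t0\t100\t0.5",
               "c1\t100\t101\t0.2", "c1\t102\t103\t0.8"), f)
  tr <- read_score_track(f, "bedgraph")
  flat <- conservation_at_sites(data.frame(chrom = "c1", pos = 50), tr)
  expect_equal(flat$score, 0.5)
  mixed <- conservation_at_sites(data.frame(chrom = "c1", pos = 101), tr)
  expect_equal(mixed$score, 0.5)  # mean(0.2, 0.8)
  # one flank missing: the present flank is used
  edge <- conservation_at_sites(data.frame(chrom = "c1", pos = 103), tr)
  expect_equal(edge$score, 0.8)
  # both flanks missing: dropped
  gone <- conservation_at_sites(data.frame(chrom = "c1", pos = 500), tr)
  expect_equal(nrow(gone), 0)
  # exclusion sets drop positions before scoring
  excl <- conservation_at_sites(data.frame(chrom = "c1", pos = c(50, 101)),
                                tr, list(gintervals("c1", 40, 60)))
  expect_equal(excl$pos, 101)
})

test_that("one-sided paired system comparison matches the closed form", {
  same <- compare_group_scores(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(same$p, 0.5)

  a <- c(0.30, 0.33, 0.27, 0.31); b <- c(0.20, 0.22, 0.18, 0.21)
  got <- compare_group_scores(a, b)
  oracle <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(got$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(got$df, 3)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
  expect_error(compare_group_scores(0.3, 0.2), "at least 2")
})
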