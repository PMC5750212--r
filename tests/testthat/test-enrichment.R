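bg_tiling <- function(n = 40, chrom = "chr1") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = seq(1, by = 500,
                                                      length.out = n),
                                          width = 500))
}

test_that("window overlap counting honors the f >= 0.1 rule", {
  bg <- bg_tiling(10)
  target <- bg[1:4]
  # track covering exactly 50 bp of window 1 (10% of 500) and 49 bp of window 5
  track <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = c(1, 2001),
                                                   width = c(50, 49)))
  tab <- windowed_overlap_counts(target, track, bg)
  expect_equal(tab$a, 1)     # window 1: 50/500 = 0.1 counted
  expect_equal(tab$b, 3)
  expect_equal(tab$c, 0)     # window 5: 49/500 < 0.1 not counted
  expect_equal(tab$d, 6)
})

test_that("a track covering everything degenerates the table", {
  bg <- bg_tiling(6)
  track <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e4))
  tab <- windowed_overlap_counts(bg[1:2], track, bg)
  expect_equal(tab$b + tab$d, 0)
  expect_true(tab$degenerate)
  res <- fisher_or(tab)
  expect_true(res$corrected)
  expect_error(windowed_overlap_counts(bg[1], track,
                                       GenomicRanges::GRanges()), "empty")
})

test_that("odds ratios and Fisher p match enumeration and the paper conventions", {
  res <- fisher_or(3, 7, 2, 8)
  expect_equal(res$odds_ratio, 24 / 14, tolerance = 1e-12)
  expect_equal(res$fisher_p, oracle_fisher_p(3, 7, 2, 8), tolerance = 1e-10)
  # density-derived odds ratios
  expect_equal(round(odds_ratio_from_props(0.0255, 0.0215), 2), 1.19)
  expect_equal(round(odds_ratio_from_props(1742 / 3217, 0.311), 2), 2.62)
  expect_equal(odds_ratio_from_props(0.3, 0.3), 1)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration for n <= 60", {
  set.seed(13)
  for (i in 1:40) {
    total <- sample(8:60, 1)
    cells <- as.numeric(table(factor(sample(1:4, total, replace = TRUE),
                                     levels = 1:4)))
    res <- fisher_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(res$fisher_p,
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("OR row-scaling invariance and row-swap inversion hold", {
  base <- fisher_or(20, 80, 10, 90)
  scaled <- fisher_or(200, 800, 10, 90)   # row 1 scaled by 10
  expect_equal(scaled$odds_ratio, base$odds_ratio, tolerance = 1e-12)
  swapped <- fisher_or(10, 90, 20, 80)
  expect_equal(swapped$odds_ratio, 1 / base$odds_ratio, tolerance = 1e-12)
  expect_true(base$ci95[1] <= base$odds_ratio &&
                base$odds_ratio <= base$ci95[2])
})

test_that("random tracks and targets give OR near 1 as counts grow", {
  set.seed(17)
  n <- 4000
  bg <- bg_tiling(n)
  target <- rbinom(n, 1, 0.3) == 1
  hit_idx <- rbinom(n, 1, 0.4) == 1
  track <- GenomicRanges::reduce(bg[hit_idx])
  tab <- windowed_overlap_counts(target, track, bg)
  res <- fisher_or(tab)
  expect_gt(res$fisher_p, 1e-3)
  expect_lt(abs(log(res$odds_ratio)), 0.35)
})

test_that("tissue-panel fold enrichment is the base-pair proportion ratio", {
  bg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = c(1001, 20001),
                                                   width = 500))
  # track containing all peaks and 10% of the background
  track_x <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1, 20001), width = c(9500, 500)))
  track_flat <- bg   # equals background coverage -> fold 1
  out <- tissue_panel_fold(peaks, list(X = track_x, flat = track_flat), bg)
  expect_equal(out$fold[out$track == "flat"], 1)
  expect_equal(out$log2_fold[out$track == "flat"], 0)
  expect_equal(out$fold[out$track == "X"], 10)
  expect_true(out$chisq_p[out$track == "X"] < 0.05)
  expect_equal(attr(out, "n_nominal"), 1)
})

test_that("a null panel is nominally significant at roughly the 5% rate", {
  # the bp-count chi-squared assumes independent base pairs, so the null
  # must be random at the unit of counting: single-bp background elements
  set.seed(37)
  n <- 4000
  bg <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = seq_len(n) * 10L,
                                                width = 1))
  peaks <- GenomicRanges::reduce(bg[sample(n, 400)])
  tracks <- lapply(1:40, function(i) GenomicRanges::reduce(bg[sample(n, 1600)]))
  names(tracks) <- paste0("t", 1:40)
  out <- tissue_panel_fold(peaks, tracks, bg)
  # expected fraction 0.05; 8+ of 40 nominal hits would be wildly miscalibrated
  expect_lt(mean(out$chisq_p < 0.05), 0.2)
  expect_lt(abs(median(out$log2_fold)), 0.2)
})

test_that("a construction-enriched track has the maximal fold in its panel", {
  sim <- desk_sim()
  scan <- desk_scan()
  peaks <- scan$peaks
  truth_gr <- GenomicRanges::GRanges(
    sim$truth$chrom, IRanges::IRanges(sim$truth$start + 1L, sim$truth$end))
  bg <- GenomicRanges::reduce(sim$blocks)
  set.seed(23)
  decoys <- lapply(1:3, function(i) {
    idx <- sample(length(sim$windows), 30)
    GenomicRanges::reduce(sim$windows[idx])
  })
  tracks <- c(list(planted = GenomicRanges::reduce(truth_gr)), decoys)
  names(tracks) <- c("planted", "d1", "d2", "d3")
  out <- tissue_panel_fold(peaks, tracks, bg)
  expect_equal(out$track[which.max(out$fold)], "planted")
})

test_that("SNP-set overlap counts points on boundaries as inside", {
  bg <- bg_tiling(20)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  snps <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(start = c(1001, 2000, 5000),
                                                  width = 1))
  snps$is_cpg_snp <- c(TRUE, FALSE, TRUE)
  res <- snp_set_overlap(peaks, snps, bg)
  expect_equal(res$n_in_peaks, 2)   # both boundary SNPs inside
  expect_equal(res$frac_cpg_in_peaks, 0.5)
  # all SNPs outside peaks -> a = 0, corrected OR < 1
  bg2 <- bg_tiling(40)
  peaks2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000))
  far <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(6001, 9001, 12001, 15001), width = 1))
  res2 <- snp_set_overlap(peaks2, far, bg2)
  expect_equal(res2$table$a, 0)
  expect_true(res2$test$corrected)
  expect_lt(res2$test$odds_ratio, 1)
})

test_that("a planted SNP enrichment is recovered within binomial error", {
  set.seed(29)
  n <- 3000
  bg <- bg_tiling(n)
  in_peak <- seq_len(n) <= 300
  peaks <- GenomicRanges::reduce(bg[in_peak])
  # SNP placement 5x denser inside peaks
  p_in <- 0.5; p_out <- 0.1
  has_snp <- rbinom(n, 1, ifelse(in_peak, p_in, p_out)) == 1
  snps <- GenomicRanges::resize(bg[has_snp], width = 1, fix = "center")
  res <- snp_set_overlap(peaks, snps, bg)
  prop_in <- res$table$a / (res$table$a + res$table$b)
  prop_out <- res$table$c / (res$table$c + res$table$d)
  fold <- prop_in / prop_out
  se <- fold * sqrt((1 - p_in) / (p_in * 300) + (1 - p_out) / (p_out * 2700))
  expect_lt(abs(fold - 5), 2 * se)
})
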