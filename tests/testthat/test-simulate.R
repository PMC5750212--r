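small_cfg <- function(...) {
  simulation_config(n_disc = 40, n_foll = 60, n_repl = 40, n_blocks = 3,
                    block_length_bp = 2000,
                    effect_windows = data.frame(block = 2L, window = 3L,
                                                type = "cpg_snp",
                                                kappa = 1.5),
                    seed = 5, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_disc = 0), "positive")
  expect_error(simulation_config(maf = 0.005), "common-SNP")
  expect_error(simulation_config(noise_sd = 0), "positive")
  expect_error(simulation_config(sib_fraction = 0.8,
                                 longitudinal_fraction = 0.5), "sum")
  expect_error(simulation_config(
    effect_windows = data.frame(block = 99L, window = 1L,
                                type = "cpg_snp", kappa = 1)), "grid")
  expect_error(simulation_config(
    effect_windows = data.frame(block = 1L, window = 999L,
                                type = "cpg_snp", kappa = 1)), "grid")
})

test_that("the same seed reproduces the simulation exactly", {
  s1 <- simulate_cohorts(small_cfg())
  s2 <- simulate_cohorts(small_cfg())
  expect_identical(s1$cohorts[["1DISC"]]$genotypes,
                   s2$cohorts[["1DISC"]]$genotypes)
  expect_identical(s1$cohorts[["2FOLL"]]$scores, s2$cohorts[["2FOLL"]]$scores)
  expect_identical(s1$truth, s2$truth)
})

test_that("homozygous CNV deletion carriers have near-zero raw signal", {
  cfg <- simulation_config(
    n_disc = 400, n_foll = 60, n_repl = 40, n_blocks = 3,
    block_length_bp = 2000,
    effect_windows = data.frame(block = 1L, window = 2L,
                                type = "cnv_deletion", kappa = 1),
    covariate_effect_sizes = numeric(), family_variance = 0,
    pair_variance = 0, seed = 8)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[["1DISC"]]
  g <- co$genotypes[sim$truth$rsid[1], ]
  w <- sim$truth$window_id[1]
  hom <- co$scores[w, g == 2]
  expect_gt(length(hom), 5)
  expect_lt(abs(mean(hom)), 3 * sd(hom) / sqrt(length(hom)) + 0.2)
  # heterozygotes sit near half the baseline signal
  het <- co$scores[w, g == 1]
  wt <- co$scores[w, g == 0]
  expect_equal(mean(het) / mean(wt), 0.5, tolerance = 0.15)
})

test_that("truth windows are a subset of the tiled windows", {
  sim <- simulate_cohorts(small_cfg())
  expect_true(all(sim$truth$window_id %in% sim$windows$window_id))
  # 2FOLL families with >1 member exist and longitudinal repeats share genotypes
  meta2 <- sim$cohorts[["2FOLL"]]$meta
  expect_gt(max(table(meta2$family_id)), 1)
  rep_idx <- which(meta2$family_id %in%
                     sim$cohorts[["1DISC"]]$meta$family_id)
  expect_gt(length(rep_idx), 0)
  i <- rep_idx[1]
  src <- match(meta2$family_id[i], sim$cohorts[["1DISC"]]$meta$family_id)
  expect_identical(unname(sim$cohorts[["2FOLL"]]$genotypes[, i]),
                   unname(sim$cohorts[["1DISC"]]$genotypes[, src]))
})

test_that("under a null configuration no window passes the Bonferroni consensus", {
  cfg <- simulation_config(
    n_disc = 60, n_foll = 80, n_repl = 60, n_blocks = 4,
    block_length_bp = 2000,
    effect_windows = data.frame(block = integer(), window = integer(),
                                type = character(), kappa = numeric()),
    seed = 12)
  sim <- simulate_cohorts(cfg)
  scan <- suppressMessages(run_hsm_pipeline(sim, engine_foll = "lm"))
  expect_equal(sum(scan$consensus$passes), 0)
  expect_equal(length(scan$peaks), 0)
})

test_that("doubling kappa never decreases the planted windows' significance", {
  run_med_logp <- function(kappa) {
    cfg <- simulation_config(
      n_disc = 80, n_foll = 60, n_repl = 40, n_blocks = 3,
      block_length_bp = 2000,
      effect_windows = data.frame(block = 1:3, window = c(2L, 4L, 6L),
                                  type = "cpg_snp", kappa = kappa),
      seed = 19)
    sim <- simulate_cohorts(cfg)
    co <- sim$cohorts[["1DISC"]]
    qqn <- qq_normalize(rpm_normalize(co$scores, co$library_sizes))
    p <- vapply(seq_len(nrow(sim$truth)), function(i) {
      scan_association(qqn[sim$truth$window_id[i], , drop = FALSE],
                       co$genotypes[sim$truth$rsid[i], ], co$meta,
                       cohort = "1DISC")$p_value
    }, numeric(1))
    median(-log10(p))
  }
  expect_gte(run_med_logp(1.0), run_med_logp(0.5))
  expect_gte(run_med_logp(2.0), run_med_logp(1.0))
})

test_that("between-family score variance approaches the family variance component", {
  cfg <- simulation_config(
    n_disc = 40, n_foll = 1200, n_repl = 40, n_blocks = 1,
    block_length_bp = 2000, sib_fraction = 1, longitudinal_fraction = 0,
    covariate_effect_sizes = numeric(), family_variance = 0.8,
    pair_variance = 0, noise_sd = 1,
    effect_windows = data.frame(block = integer(), window = integer(),
                                type = character(), kappa = numeric()),
    seed = 23)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[["2FOLL"]]
  w <- sim$windows$window_id[1]
  fam_means <- tapply(co$scores[w, ], co$meta$family_id, mean)
  fam_sizes <- table(co$meta$family_id)
  # var(family mean) = family_variance + noise^2 / pair size
  expected <- 0.8 + 1 / mean(fam_sizes)
  expect_equal(var(as.numeric(fam_means)), expected, tolerance = 0.25)
})

test_that("fixture files round-trip through the readers and are deterministic", {
  cfg <- simulation_config(n_disc = 5, n_foll = 6, n_repl = 5, n_blocks = 2,
                           block_length_bp = 1000,
                           effect_windows = data.frame(
                             block = 1L, window = 2L, type = "cnv_deletion",
                             kappa = 1), seed = 4)
  sim <- simulate_cohorts(cfg)
  out1 <- file.path(tempdir(), "fix1"); out2 <- file.path(tempdir(), "fix2")
  unlink(c(out1, out2), recursive = TRUE)
  f1 <- emit_fixture_files(sim, out1)
  f2 <- emit_fixture_files(sim, out2)
  expect_equal(length(f1), length(f2))
  # determinism: byte-identical files
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  # one genotype table row per sample x SNP, one BED per sample
  g <- utils::read.delim(file.path(out1, "genotypes_1DISC.tsv"))
  expect_equal(nrow(g), 5 * 2)
  beds <- list.files(file.path(out1, "window_counts_1DISC"))
  expect_length(beds, 5)
  # round-trip: map -> blocks reconstructs the simulated blocks
  map <- read_genetic_map(file.path(out1, "genetic_map.tsv"))
  cat_df <- read_gwas_catalogue(file.path(out1, "gwas_catalogue.tsv"))
  bb <- build_blocks(map, cat_df)
  expect_equal(GenomicRanges::start(bb$blocks),
               GenomicRanges::start(sim$blocks))
  expect_equal(GenomicRanges::end(bb$blocks), GenomicRanges::end(sim$blocks))
  # round-trip: window counts
  rt <- read_window_counts(file.path(out1, "window_counts_1DISC"))
  expect_equal(rownames(rt$scores), sim$windows$window_id)
  expect_equal(unname(rt$scores[, "D0001"]),
               as.numeric(sprintf("%.6g", sim$cohorts[["1DISC"]]$scores[, "D0001"])))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("an empty cohort list warns and writes nothing", {
  sim <- simulate_cohorts(small_cfg())
  sim$cohorts <- list()
  expect_warning(out <- emit_fixture_files(sim, tempdir()), "no cohorts")
  expect_length(out, 0)
})
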