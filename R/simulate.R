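#' Configuration for the synthetic three-cohort simulation
#'
#' Defines the study conditions the generator emulates: three cohorts (a
#' discovery set of unrelated individuals, a follow-up set containing
#' sibling pairs and longitudinal repeats of discovery individuals, and an
#' unrelated replication set), LD blocks on one synthetic chromosome with
#' one GWAS-tagging SNP each, 500 bp / 250 bp-slide window scores whose
#' expectation follows methylated-CpG dosage per haplotype, covariate
#' effects, and family / individual variance components.
#'
#' @param seed integer master seed; fans out to per-cohort streams.
#' @param n_disc,n_foll,n_repl samples per cohort.
#' @param n_blocks number of LD blocks (one tagging SNP per block).
#' @param block_length_bp block length in bp (multiple of 250, >= 500).
#' @param maf minor allele frequency of tagging SNPs; at least 0.01
#'   (the common-SNP convention).
#' @param effect_windows data.frame of planted effects with columns
#'   `block` (1-based block index), `window` (1-based window index within
#'   the block), `type` (one of "cpg_snp", "cnv_deletion", "str", "null")
#'   and `kappa` (score units per allele; ignored for "cnv_deletion",
#'   whose effect is the multiplicative copy-loss `(2 - d) / 2`).
#' @param covariate_effect_sizes named numeric slopes applied to numeric
#'   metadata columns (e.g. `c(age = 0.02, lymphocytes = 1)`).
#' @param noise_sd residual score standard deviation (> 0).
#' @param sib_fraction fraction of the follow-up cohort composed of
#'   sibling-pair samples.
#' @param longitudinal_fraction fraction of the follow-up cohort that are
#'   repeat time-points of discovery individuals.
#' @param family_variance,pair_variance variance components of the family
#'   and individual (within-family) random intercepts, score units squared.
#' @param baseline mean raw window score (score units).
#' @param ld_r2 squared correlation between the tagging SNP and the causal
#'   variant; 1 (default) places the causal variant on the tagged
#'   haplotype itself.
#' @return validated list of class `"hsm_sim_config"`.
#' @export
simulation_config <- function(seed = 17L, n_disc = 200L, n_foll = 300L,
                              n_repl = 200L, n_blocks = 20L,
                              block_length_bp = 4000L, maf = 0.3,
                              effect_windows = default_effect_windows(),
                              covariate_effect_sizes = c(age = 0.02,
                                                         lymphocytes = 1),
                              noise_sd = 1, sib_fraction = 0.4,
                              longitudinal_fraction = 0.2,
                              family_variance = 0.2, pair_variance = 0.1,
                              baseline = 10, ld_r2 = 1) {
  cfg <- list(seed = as.integer(seed), n_disc = as.integer(n_disc),
              n_foll = as.integer(n_foll), n_repl = as.integer(n_repl),
              n_blocks = as.integer(n_blocks),
              block_length_bp = as.integer(block_length_bp), maf = maf,
              effect_windows = effect_windows,
              covariate_effect_sizes = covariate_effect_sizes,
              noise_sd = noise_sd, sib_fraction = sib_fraction,
              longitudinal_fraction = longitudinal_fraction,
              family_variance = family_variance,
              pair_variance = pair_variance, baseline = baseline,
              ld_r2 = ld_r2)
  if (any(c(cfg$n_disc, cfg$n_foll, cfg$n_repl, cfg$n_blocks) <= 0))
    stop("sample and block counts must be positive")
  if (cfg$maf < 0.01 || cfg$maf > 1)
    stop("maf must lie in [0.01, 1] (common-SNP convention)")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  fr <- c(cfg$sib_fraction, cfg$longitudinal_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("cohort composition fractions must lie in [0,1] and sum to <= 1")
  if (cfg$family_variance < 0 || cfg$pair_variance < 0)
    stop("variance components must be non-negative")
  if (cfg$block_length_bp < 500 || cfg$block_length_bp %% 250 != 0)
    stop("block_length_bp must be >= 500 and a multiple of 250")
  n_win <- (cfg$block_length_bp - 500L) %/% 250L + 1L
  ew <- cfg$effect_windows
  if (nrow(ew)) {
    if (!all(ew$type %in% c("cpg_snp", "cnv_deletion", "str", "null")))
      stop("unknown effect type")
    if (any(ew$block < 1 | ew$block > cfg$n_blocks))
      stop("effect block outside the simulated grid")
    if (any(ew$window < 1 | ew$window > n_win))
      stop("effect window outside the simulated grid")
  }
  cfg$windows_per_block <- n_win
  structure(cfg, class = "hsm_sim_config")
}

#' Default planted-effect layout (5 effects across 20 blocks)
#' @return data.frame with columns block, window, type, kappa.
#' @export
default_effect_windows <- function() {
  data.frame(
    block = c(3L, 6L, 10L, 14L, 18L),
    window = c(3L, 8L, 5L, 11L, 7L),
    type = c("cpg_snp", "cnv_deletion", "str", "cpg_snp", "cnv_deletion"),
    kappa = 1.0,
    stringsAsFactors = FALSE
  )
}

# Genome layout: blocks on "chr1" separated by 1 kb spacers; recombination
# walls (rate 15 cM/Mb) at both ends of every block, low-rate points inside.
sim_layout <- function(cfg) {
  L <- cfg$block_length_bp
  wall_up <- (seq_len(cfg$n_blocks) - 1L) * (L + 1000L) + 1000L
  wall_down <- wall_up + L
  blocks <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = wall_up + 1L, end = wall_down),
    block_id = sprintf("chr1:%d-%d", wall_up, wall_down)
  )
  names(blocks) <- blocks$block_id
  interior <- lapply(seq_len(cfg$n_blocks), function(i)
    round(wall_up[i] + L * c(0.25, 0.5, 0.75)))
  map <- data.frame(
    chrom = "chr1",
    pos = c(wall_up, wall_down, unlist(interior)),
    rate = c(rep(15, 2L * cfg$n_blocks),
             rep(0.5, 3L * cfg$n_blocks))
  )
  map <- map[!duplicated(map$pos), ]
  map <- map[order(map$pos), ]
  snp_pos <- wall_up + L %/% 2L
  catalogue <- data.frame(
    rsid = sprintf("rs%04d", seq_len(cfg$n_blocks)),
    chrom = "chr1", pos = snp_pos,
    trait = "synthetic_trait", p = 1e-9, stringsAsFactors = FALSE
  )
  list(blocks = blocks, map = map, catalogue = catalogue,
       chrom_sizes = c(chr1 = max(wall_down) + 1000L))
}

sim_truth <- function(cfg, layout, windows) {
  ew <- cfg$effect_windows
  if (!nrow(ew)) return(ew)
  idx_by_block <- split(seq_along(windows), windows$parent_block)
  ord <- layout$blocks$block_id
  rows <- lapply(seq_len(nrow(ew)), function(i) {
    bid <- ord[ew$block[i]]
    widx <- idx_by_block[[bid]][ew$window[i]]
    w <- windows[widx]
    data.frame(block_id = bid, window_id = w$window_id,
               chrom = as.character(GenomicRanges::seqnames(w)),
               start = GenomicRanges::start(w) - 1L,
               end = GenomicRanges::end(w),
               type = ew$type[i], kappa = ew$kappa[i],
               rsid = layout$catalogue$rsid[ew$block[i]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Mendelian transmission: child haplotypes drawn from two parents whose
# haplotypes are Bernoulli(maf) per SNP. Returns genotype matrix snps x 2.
sib_pair_genotypes <- function(n_snps, maf, mz) {
  pat <- matrix(stats::rbinom(n_snps * 2L, 1L, maf), ncol = 2L)
  mat <- matrix(stats::rbinom(n_snps * 2L, 1L, maf), ncol = 2L)
  draw_child <- function() {
    pat[cbind(seq_len(n_snps), sample(1:2, n_snps, replace = TRUE))] +
      mat[cbind(seq_len(n_snps), sample(1:2, n_snps, replace = TRUE))]
  }
  c1 <- draw_child()
  c2 <- if (mz) c1 else draw_child()
  cbind(c1, c2)
}

sim_metadata <- function(sample_ids, cohort, sex = NULL) {
  n <- length(sample_ids)
  data.frame(
    sample_id = sample_ids,
    age = round(stats::runif(n, 20, 80), 1),
    sex = if (is.null(sex)) sample(c("F", "M"), n, replace = TRUE) else sex,
    lymphocytes = round(stats::runif(n, 0.15, 0.45), 4),
    monocytes = round(stats::runif(n, 0.02, 0.12), 4),
    neutrophils = round(stats::runif(n, 0.35, 0.70), 4),
    eosinophils = round(stats::runif(n, 0.00, 0.08), 4),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE),
    batch = sample(paste0("b", 1:4), n, replace = TRUE),
    cohort = cohort,
    stringsAsFactors = FALSE
  )
}

covariate_shift <- function(meta, effect_sizes) {
  shift <- numeric(nrow(meta))
  for (nm in names(effect_sizes)) {
    if (nm == "sex") {
      shift <- shift + effect_sizes[[nm]] * (meta$sex == "M")
    } else if (nm %in% names(meta) && is.numeric(meta[[nm]])) {
      shift <- shift + effect_sizes[[nm]] * meta[[nm]]
    }
  }
  shift
}

# Raw window scores for one cohort given genotypes and random intercepts.
# Expectation per sample i, window w:
#   mu_w * cnv_multiplier + kappa_w * g_i + covariates + u_family + u_indiv
# with Gaussian noise; cnv carriers of d deleted copies scale mu_w by
# (2 - d)/2 (homozygous deletion -> zero signal).
sim_scores <- function(cfg, windows, window_mu, truth, genotypes, meta,
                       fam_int, ind_int) {
  n_win <- length(windows)
  n_smp <- nrow(meta)
  sc <- matrix(window_mu, nrow = n_win, ncol = n_smp,
               dimnames = list(windows$window_id, meta$sample_id))
  if (!is.null(truth) && nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      wi <- match(truth$window_id[i], windows$window_id)
      g <- genotypes[truth$rsid[i], ]
      if (cfg$ld_r2 < 1) g <- degrade_ld(g, cfg$maf, cfg$ld_r2)
      if (truth$type[i] == "cnv_deletion") {
        sc[wi, ] <- sc[wi, ] * (2 - g) / 2
      } else if (truth$type[i] != "null") {
        sc[wi, ] <- sc[wi, ] + truth$kappa[i] * g
      }
    }
  }
  shift <- covariate_shift(meta, cfg$covariate_effect_sizes)
  re <- fam_int[meta$family_id] + ind_int[paste(meta$family_id,
                                                meta$individual_id,
                                                sep = ":")]
  sc <- sweep(sc, 2L, shift + re, "+")
  sc + matrix(stats::rnorm(n_win * n_smp, 0, cfg$noise_sd), nrow = n_win)
}

#' Simulate three synthetic cohorts with planted haplotype effects
#'
#' Generates the full input set for the pipeline: a genetic map with
#' recombination walls delimiting the LD blocks, a GWAS catalogue with one
#' tagging SNP per block, per-cohort genotypes (Hardy-Weinberg draws for
#' unrelated individuals, Mendelian transmission within sibling families,
#' identical genotypes for monozygotic twins and for longitudinal repeats),
#' sample metadata, and raw window-score matrices following the generative
#' model described in [simulation_config()]. The master seed fans out to
#' independent per-cohort streams, so cohorts are reproducible in
#' isolation.
#'
#' @param config an `"hsm_sim_config"` from [simulation_config()].
#' @return list of class `"hsm_simulation"`: config, map, catalogue,
#'   blocks, windows, chrom_sizes, truth, blacklist (decoy GRanges),
#'   variants (named list of GRanges), snp_contexts, and `cohorts` - a
#'   named list ("1DISC", "2FOLL", "3REPL") each holding genotypes
#'   (SNP x sample matrix), scores (window x sample raw matrix),
#'   library_sizes and meta.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "hsm_sim_config"))
  layout <- sim_layout(config)
  windows <- tile_windows(layout$blocks)
  truth <- sim_truth(config, layout, windows)

  set.seed(config$seed)
  window_mu <- config$baseline + stats::rnorm(length(windows), 0, 0.5)
  sub_seeds <- sample.int(2^30, 4L)
  n_snps <- config$n_blocks
  rsids <- layout$catalogue$rsid

  ## ---- 1DISC: unrelated, female-only ----
  set.seed(sub_seeds[1])
  n1 <- config$n_disc
  ids1 <- sprintf("D%04d", seq_len(n1))
  g1 <- matrix(stats::rbinom(n_snps * n1, 2L, config$maf), nrow = n_snps,
               dimnames = list(rsids, ids1))
  meta1 <- sim_metadata(ids1, "1DISC", sex = "F")
  meta1$family_id <- sprintf("F%04d", seq_len(n1))
  meta1$individual_id <- sprintf("I%04d", seq_len(n1))
  meta1$zygosity <- NA_character_
  fam1 <- stats::setNames(
    stats::rnorm(n1, 0, sqrt(config$family_variance)), meta1$family_id)
  ind1 <- stats::setNames(
    stats::rnorm(n1, 0, sqrt(config$pair_variance)),
    paste(meta1$family_id, meta1$individual_id, sep = ":"))
  sc1 <- sim_scores(config, windows, window_mu, truth, g1, meta1,
                    fam1, ind1)
  lib1 <- round(stats::runif(n1, 0.9e6, 1.1e6))

  ## ---- 2FOLL: longitudinal repeats + sibling pairs + singletons ----
  set.seed(sub_seeds[2])
  n2 <- config$n_foll
  n_long <- round(config$longitudinal_fraction * n2)
  n_sib_pairs <- floor(config$sib_fraction * n2 / 2)
  n_single <- n2 - n_long - 2L * n_sib_pairs
  ids2 <- sprintf("L%04d", seq_len(n2))

  g2 <- matrix(0L, nrow = n_snps, ncol = n2,
               dimnames = list(rsids, ids2))
  fam2 <- character(n2); ind2 <- character(n2); zyg2 <- rep(NA_character_, n2)
  fam_int2 <- fam1
  ind_int2 <- ind1

  k <- 0L
  long_src <- sample(seq_len(config$n_disc), n_long,
                     replace = n_long > config$n_disc)
  for (j in seq_len(n_long)) {
    k <- k + 1L
    src <- long_src[j]
    g2[, k] <- g1[, src]
    fam2[k] <- meta1$family_id[src]
    ind2[k] <- meta1$individual_id[src]
  }
  for (p in seq_len(n_sib_pairs)) {
    fid <- sprintf("SF%04d", p)
    mz <- stats::runif(1) < 0.4
    gg <- sib_pair_genotypes(n_snps, config$maf, mz)
    u_f <- stats::rnorm(1, 0, sqrt(config$family_variance))
    fam_int2[fid] <- u_f
    for (s in 1:2) {
      k <- k + 1L
      g2[, k] <- gg[, s]
      fam2[k] <- fid
      ind2[k] <- sprintf("SI%04d_%d", p, s)
      zyg2[k] <- if (mz) "MZ" else "DZ"
      ind_int2[paste(fid, ind2[k], sep = ":")] <-
        stats::rnorm(1, 0, sqrt(config$pair_variance))
    }
  }
  for (s in seq_len(n_single)) {
    k <- k + 1L
    g2[, k] <- stats::rbinom(n_snps, 2L, config$maf)
    fam2[k] <- sprintf("UF%04d", s)
    ind2[k] <- sprintf("UI%04d", s)
    fam_int2[fam2[k]] <- stats::rnorm(1, 0, sqrt(config$family_variance))
    ind_int2[paste(fam2[k], ind2[k], sep = ":")] <-
      stats::rnorm(1, 0, sqrt(config$pair_variance))
  }
  meta2 <- sim_metadata(ids2, "2FOLL")
  meta2$family_id <- fam2
  meta2$individual_id <- ind2
  meta2$zygosity <- zyg2
  sc2 <- sim_scores(config, windows, window_mu, truth, g2, meta2,
                    fam_int2, ind_int2)
  lib2 <- round(stats::runif(n2, 0.9e6, 1.1e6))

  ## ---- 3REPL: unrelated ----
  set.seed(sub_seeds[3])
  n3 <- config$n_repl
  ids3 <- sprintf("R%04d", seq_len(n3))
  g3 <- matrix(stats::rbinom(n_snps * n3, 2L, config$maf), nrow = n_snps,
               dimnames = list(rsids, ids3))
  meta3 <- sim_metadata(ids3, "3REPL")
  meta3$family_id <- sprintf("RF%04d", seq_len(n3))
  meta3$individual_id <- sprintf("RI%04d", seq_len(n3))
  meta3$zygosity <- NA_character_
  fam3 <- stats::setNames(
    stats::rnorm(n3, 0, sqrt(config$family_variance)), meta3$family_id)
  ind3 <- stats::setNames(
    stats::rnorm(n3, 0, sqrt(config$pair_variance)),
    paste(meta3$family_id, meta3$individual_id, sep = ":"))
  sc3 <- sim_scores(config, windows, window_mu, truth, g3, meta3,
                    fam3, ind3)
  lib3 <- round(stats::runif(n3, 0.9e6, 1.1e6))

  ## ---- annotation fixtures tied to the truth ----
  set.seed(sub_seeds[4])
  variants <- sim_variant_tracks(truth, layout)
  blacklist <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = 200L, end = 700L))  # spacer decoy
  snp_contexts <- sim_snp_contexts(layout, truth)

  structure(list(
    config = config, map = layout$map, catalogue = layout$catalogue,
    blocks = layout$blocks, windows = windows,
    chrom_sizes = layout$chrom_sizes, truth = truth,
    blacklist = blacklist, variants = variants,
    snp_contexts = snp_contexts,
    cohorts = list(
      "1DISC" = list(genotypes = g1, scores = sc1, library_sizes = lib1,
                     meta = meta1),
      "2FOLL" = list(genotypes = g2, scores = sc2, library_sizes = lib2,
                     meta = meta2),
      "3REPL" = list(genotypes = g3, scores = sc3, library_sizes = lib3,
                     meta = meta3)
    )), class = "hsm_simulation")
}

# Decouple the causal variant from the tagging SNP: allele-wise, the causal
# allele copies the tagged allele with probability sqrt(r2), otherwise it is
# redrawn at the population frequency, giving haplotype correlation ~ r.
degrade_ld <- function(g, maf, r2) {
  h1 <- pmin(g, 1L)
  h2 <- g - h1
  copy_or_redraw <- function(h) {
    keep <- stats::rbinom(length(h), 1L, sqrt(r2))
    ifelse(keep == 1L, h, stats::rbinom(length(h), 1L, maf))
  }
  copy_or_redraw(h1) + copy_or_redraw(h2)
}

sim_variant_tracks <- function(truth, layout) {
  gr_of <- function(d) {
    if (is.null(d) || nrow(d) == 0L)
      return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(d$chrom,
                           IRanges::IRanges(start = d$start + 1L,
                                            end = d$end))
  }
  spacer_decoy <- function(offset)
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(start = offset, width = 200L))
  cnv <- gr_of(truth[truth$type == "cnv_deletion", , drop = FALSE])
  str_ <- gr_of(truth[truth$type == "str", , drop = FALSE])
  list(CNV = cnv, STR = str_,
       eSTR = spacer_decoy(100L), Indel = spacer_decoy(500L))
}

# Tagging-SNP sequence contexts: cpg_snp-planted SNPs get a C/T allele pair
# ahead of a G (CpG created/lost); all others are A/G in a neutral context.
sim_snp_contexts <- function(layout, truth) {
  ctx <- data.frame(
    rsid = layout$catalogue$rsid, chrom = layout$catalogue$chrom,
    pos = layout$catalogue$pos, alleles = "A,G", flank5 = "T",
    flank3 = "T", maf = 0.3, stringsAsFactors = FALSE)
  if (!is.null(truth) && nrow(truth)) {
    cpg_rsids <- truth$rsid[truth$type == "cpg_snp"]
    sel <- ctx$rsid %in% cpg_rsids
    ctx$alleles[sel] <- "C,T"
    ctx$flank5[sel] <- "A"
    ctx$flank3[sel] <- "G"
  }
  ctx
}

#' Write simulation fixtures to disk
#'
#' Emits the file set consumed by the readers of the downstream modules:
#' genetic-map, GWAS-catalogue, chromosome-sizes, truth, per-cohort
#' genotype / metadata / library-size TSVs, per-sample window-count BED
#' files (0-based half-open), variant BEDs, a blacklist BED and the
#' SNP-context TSV. Re-running with the same simulation yields
#' byte-identical files.
#'
#' @param sim an `"hsm_simulation"` from [simulate_cohorts()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the character vector of files written. An empty
#'   simulation produces no files and a warning.
#' @export
emit_fixture_files <- function(sim, outdir) {
  stopifnot(inherits(sim, "hsm_simulation"))
  if (length(sim$cohorts) == 0L) {
    warning("no cohorts to write")
    return(invisible(character()))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  written <- character()
  tsv <- function(d, name) {
    path <- file.path(outdir, name)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }
  bed <- function(gr, name, extra = NULL) {
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
    if (!is.null(extra)) d <- cbind(d, extra)
    path <- file.path(outdir, name)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <<- c(written, path)
  }
  tsv(sim$map, "genetic_map.tsv")
  tsv(sim$catalogue, "gwas_catalogue.tsv")
  tsv(data.frame(chrom = names(sim$chrom_sizes),
                 size = as.integer(sim$chrom_sizes)), "chrom_sizes.tsv")
  if (!is.null(sim$truth) && nrow(sim$truth)) tsv(sim$truth, "truth.tsv")
  tsv(sim$snp_contexts, "snp_contexts.tsv")
  bed(sim$blacklist, "blacklist.bed")
  for (cls in names(sim$variants))
    bed(sim$variants[[cls]], paste0(tolower(cls), ".bed"))

  for (cname in names(sim$cohorts)) {
    co <- sim$cohorts[[cname]]
    g_long <- data.frame(
      sample_id = rep(colnames(co$genotypes),
                      each = nrow(co$genotypes)),
      rsid = rep(rownames(co$genotypes), ncol(co$genotypes)),
      count = as.integer(co$genotypes))
    tsv(g_long, sprintf("genotypes_%s.tsv", cname))
    tsv(co$meta, sprintf("metadata_%s.tsv", cname))
    tsv(data.frame(sample_id = colnames(co$scores),
                   library_size = co$library_sizes),
        sprintf("library_sizes_%s.tsv", cname))
    cdir <- file.path(outdir, paste0("window_counts_", cname))
    dir.create(cdir, showWarnings = FALSE)
    for (s in colnames(co$scores)) {
      path <- file.path(cdir, paste0(s, ".bed"))
      utils::write.table(
        data.frame(chrom = as.character(GenomicRanges::seqnames(sim$windows)),
                   start = GenomicRanges::start(sim$windows) - 1L,
                   end = GenomicRanges::end(sim$windows),
                   count = sprintf("%.6g", co$scores[, s])),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
      written <- c(written, path)
    }
  }
  invisible(written)
}

#' Read per-sample window-count BED-like files back into a matrix
#'
#' @param dir directory of `<sample>.bed` files written by
#'   [emit_fixture_files()] (columns chrom, start0, end, count).
#' @return list: `scores` (window x sample matrix, BED-style window ids as
#'   row names) and `windows` (GRanges).
#' @export
read_window_counts <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (!length(files)) stop("no window-count files in ", dir)
  first <- utils::read.delim(files[1], header = FALSE,
                             col.names = c("chrom", "start", "end", "count"))
  windows <- GenomicRanges::GRanges(
    first$chrom, IRanges::IRanges(start = first$start + 1L,
                                  end = first$end))
  windows$window_id <- window_ids(windows)
  mat <- vapply(files, function(f)
    utils::read.delim(f, header = FALSE)[[4]], numeric(nrow(first)))
  colnames(mat) <- sub("\\.bed$", "", basename(files))
  rownames(mat) <- windows$window_id
  list(scores = mat, windows = windows)
}
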