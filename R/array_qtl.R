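#' Standardize array beta values per probe
#'
#' Each probe's methylation fractions are centered and scaled to mean 0 and
#' standard deviation 1 across samples; constant probes become `NA` rows
#' and are flagged.
#'
#' @param betas numeric matrix, probes in rows, samples in columns, values
#'   in \[0, 1\].
#' @return standardized matrix with attribute `constant_probes` (row names
#'   of flagged probes).
#' @export
standardize_betas <- function(betas) {
  betas <- as.matrix(betas)
  mu <- rowMeans(betas)
  s <- apply(betas, 1L, stats::sd)
  flagged <- rownames(betas)[s == 0]
  s[s == 0] <- NA_real_
  out <- (betas - mu) / s
  attr(out, "constant_probes") <- flagged %||% character()
  out
}

#' Prune array probes near common SNPs
#'
#' Multimap-flagged probes are removed first; then probes whose interrogated
#' CpG position lies within `distance` bp (inclusive) of a common SNP on the
#' same chromosome are removed. `distance = 0` removes probes with a SNP at
#' the interrogated position itself.
#'
#' @param manifest data.frame with columns probe_id, chrom, pos, and
#'   optionally multimap (logical).
#' @param snp_positions data.frame with columns chrom, pos (common SNPs,
#'   MAF >= 1 percent), or a GRanges of width-1 positions.
#' @param distance pruning distance in bp, conventionally 0, 10 or 50.
#' @return the retained manifest rows; attributes `n_multimap_removed` and
#'   `n_snp_removed` record the counts.
#' @export
prune_probes <- function(manifest, snp_positions, distance = 10) {
  stopifnot(distance >= 0)
  if (methods::is(snp_positions, "GRanges")) {
    snp_positions <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(snp_positions)),
      pos = GenomicRanges::start(snp_positions))
  }
  mm <- if (!is.null(manifest$multimap)) as.logical(manifest$multimap)
        else rep(FALSE, nrow(manifest))
  out <- manifest[!mm, , drop = FALSE]
  snp_by_chrom <- split(snp_positions$pos, snp_positions$chrom)
  near <- vapply(seq_len(nrow(out)), function(i) {
    sp <- snp_by_chrom[[out$chrom[i]]]
    if (is.null(sp)) return(FALSE)
    min(abs(sp - out$pos[i])) <= distance
  }, logical(1))
  res <- out[!near, , drop = FALSE]
  attr(res, "n_multimap_removed") <- sum(mm)
  attr(res, "n_snp_removed") <- sum(near)
  res
}

#' Per-probe mixed-model association with allelic count
#'
#' Standardized probe values are tested for the GWAS-SNP allelic count with
#' the same engine as the window scan: a family/individual random-intercept
#' linear mixed model compared by likelihood-ratio test to the null without
#' the genotype term, using the array covariate set (see
#' [hsm_covariates()]). Cohorts without family structure reduce exactly to
#' ordinary least squares.
#'
#' @param values numeric vector of standardized probe values (use
#'   [standardize_betas()]).
#' @param genotype numeric allelic counts (0/1/2).
#' @param meta per-sample covariate data.frame with family_id and
#'   individual_id.
#' @param covariates covariate names (default the array set).
#' @param probe_id identifier carried into the result.
#' @return one-row data.frame as in [fit_mixed()].
#' @export
probe_lmm <- function(values, genotype, meta,
                      covariates = hsm_covariates("array"),
                      probe_id = NA_character_) {
  res <- fit_mixed(values, genotype, meta, cohort = "2FOLL",
                   covariates = covariates, window_id = probe_id)
  res$cohort <- "array"
  res
}

#' Genotype-permutation empirical null for the array scan
#'
#' Each permutation applies one global shuffle of the sample-to-genotype
#' assignment (all probes see the same shuffle, preserving genotype
#' frequencies and inter-probe correlation), recomputes the per-probe scan
#' and counts probes significant at the nominal and Bonferroni levels. The
#' empirical p-value for a count statistic is
#' `(1 + #permutations >= observed) / (B + 1)`.
#'
#' @param betas probe x sample matrix of beta values (standardized
#'   internally).
#' @param genotype numeric allelic counts (0/1/2) per sample.
#' @param meta per-sample covariate data.frame.
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @param covariates covariate names (default the array set).
#' @param nominal nominal significance level (default 0.05).
#' @param bonferroni genome-wide level (default 1e-7).
#' @param engine "lm" (vectorized, default) or "lmm".
#' @return list of class `"hsm_permutation"`: observed_nominal,
#'   observed_bonferroni, perm_nominal and perm_bonferroni (vectors of
#'   length B), empirical_p_nominal, empirical_p_bonferroni, B.
#' @export
permute_genotypes <- function(betas, genotype, meta, B, seed = 1L,
                              covariates = hsm_covariates("array"),
                              nominal = 0.05, bonferroni = 1e-7,
                              engine = "lm") {
  if (B < 1L) stop("B must be at least 1")
  n <- length(genotype)
  if (lfactorial(n) < log(B)) warning("fewer distinct shuffles than B")
  std <- standardize_betas(betas)
  std <- std[stats::complete.cases(std), , drop = FALSE]
  scan_counts <- function(g) {
    res <- scan_association(std, g, meta, cohort = "array",
                            covariates = covariates, engine = engine)
    p <- res$p_value[res$status == "tested"]
    c(nominal = sum(p < nominal, na.rm = TRUE),
      bonferroni = sum(p < bonferroni, na.rm = TRUE))
  }
  obs <- scan_counts(genotype)
  set.seed(seed)
  perm <- vapply(seq_len(B), function(b) scan_counts(sample(genotype)),
                 numeric(2))
  emp <- function(observed, perms)
    (1 + sum(perms >= observed)) / (B + 1)
  structure(list(
    observed_nominal = unname(obs["nominal"]),
    observed_bonferroni = unname(obs["bonferroni"]),
    perm_nominal = unname(perm["nominal", ]),
    perm_bonferroni = unname(perm["bonferroni", ]),
    empirical_p_nominal = emp(obs["nominal"], perm["nominal", ]),
    empirical_p_bonferroni = emp(obs["bonferroni"], perm["bonferroni", ]),
    B = as.integer(B)), class = "hsm_permutation")
}

#' Simulate a methylation-array cohort with planted mQTL probes
#'
#' Synthetic inputs for the array module: beta values are inverse-logit
#' transformed Gaussian scores; planted mQTL probes carry an additive
#' genotype effect on the latent scale. A probe manifest with positions,
#' multimap flags and nearby common-SNP positions is generated alongside.
#'
#' @param n_samples samples.
#' @param n_probes probes.
#' @param n_mqtl number of planted mQTL probes (first `n_mqtl` probes).
#' @param effect latent-scale effect per allele in standard deviations
#'   (default 0.8).
#' @param maf minor allele frequency of the tagging SNP (default 0.3).
#' @param n_multimap probes flagged as multi-mapping (default 3).
#' @param n_snp_near probes given a common SNP within 10 bp (default 5).
#' @param seed integer seed.
#' @return list: betas (probe x sample), genotype, manifest,
#'   snp_positions (data.frame chrom, pos), meta, mqtl_probes.
#' @export
simulate_array_data <- function(n_samples = 300L, n_probes = 100L,
                                n_mqtl = 5L, effect = 0.8, maf = 0.3,
                                n_multimap = 3L, n_snp_near = 5L,
                                seed = 1L) {
  stopifnot(n_mqtl <= n_probes)
  set.seed(seed)
  g <- stats::rbinom(n_samples, 2L, maf)
  probe_ids <- sprintf("cg%06d", seq_len(n_probes))
  z <- matrix(stats::rnorm(n_probes * n_samples), nrow = n_probes,
              dimnames = list(probe_ids, sprintf("S%03d", seq_len(n_samples))))
  if (n_mqtl > 0)
    z[seq_len(n_mqtl), ] <- z[seq_len(n_mqtl), , drop = FALSE] +
      matrix(rep(effect * g, n_mqtl), nrow = n_mqtl, byrow = TRUE)
  betas <- stats::plogis(z - 0.5)
  pos <- 10000L + seq_len(n_probes) * 10000L
  manifest <- data.frame(
    probe_id = probe_ids, chrom = "chr1", pos = pos,
    multimap = seq_len(n_probes) %in%
      sample(seq_len(n_probes), n_multimap))
  snp_idx <- sample(which(!manifest$multimap), n_snp_near)
  snp_positions <- data.frame(chrom = "chr1",
                              pos = manifest$pos[snp_idx] + 4L)
  meta <- data.frame(
    sample_id = colnames(z),
    age = stats::runif(n_samples, 20, 80),
    smoking = sample(c("never", "former", "current"), n_samples,
                     replace = TRUE),
    beadchip = sample(paste0("chip", 1:4), n_samples, replace = TRUE),
    beadchip_pos = sample(paste0("R0", 1:6), n_samples, replace = TRUE),
    granulocytes = stats::runif(n_samples, 0.4, 0.7),
    monocytes_arr = stats::runif(n_samples, 0.02, 0.12),
    cd8t = stats::runif(n_samples, 0.05, 0.2),
    family_id = sprintf("AF%03d", seq_len(n_samples)),
    individual_id = sprintf("AI%03d", seq_len(n_samples)),
    stringsAsFactors = FALSE)
  list(betas = betas, genotype = g, manifest = manifest,
       snp_positions = snp_positions, meta = meta,
       mqtl_probes = probe_ids[seq_len(n_mqtl)])
}
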