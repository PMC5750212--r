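#' Run the full HSM scan on a simulated (or assembled) data set
#'
#' Executes the complete method: RPM and rank-inverse-normal normalization
#' of raw window scores per cohort, per-window association of normalized
#' methylation with each block's tagging-SNP allelic count (linear model in
#' the discovery cohort, family mixed model in follow-up, replication
#' reducing to OLS when unrelated), per-window aggregation across co-located
#' SNPs, a Bonferroni threshold from the number of windows tested, blacklist
#' masking (after testing, before peak calling), tri-cohort
#' significance-and-direction consensus, merging of surviving windows into
#' HSM peaks, and variant-class annotation of the peaks.
#'
#' @param sim an `"hsm_simulation"` from [simulate_cohorts()], or a list
#'   with the same structure assembled from files.
#' @param alpha family-wise error rate for the Bonferroni threshold
#'   (default 0.05).
#' @param engine_foll association engine for the follow-up cohort: "lmm"
#'   (default) or "lm".
#' @param max_gap peak merge gap in bp (default 0).
#' @return list of class `"hsm_scan"`: threshold, n_tests, results (named
#'   list of per-cohort aggregated data.frames), consensus (data.frame),
#'   peaks (annotated GRanges), summary (data.frame), recovery (data.frame
#'   of truth windows with `in_peak` flag, when truth is present).
#' @export
run_hsm_pipeline <- function(sim, alpha = 0.05, engine_foll = "lmm",
                             max_gap = 0L) {
  windows <- sim$windows
  snp_gr <- GenomicRanges::GRanges(
    sim$catalogue$chrom,
    IRanges::IRanges(start = sim$catalogue$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(snp_gr, sim$blocks)
  snp_block <- rep(NA_character_, length(snp_gr))
  snp_block[S4Vectors::queryHits(ov)] <-
    sim$blocks$block_id[S4Vectors::subjectHits(ov)]

  engines <- c("1DISC" = "lm", "2FOLL" = engine_foll, "3REPL" = "lmm")
  results <- list()
  n_tests <- 0L
  for (cname in names(sim$cohorts)) {
    co <- sim$cohorts[[cname]]
    rpm <- rpm_normalize(co$scores, co$library_sizes)
    qqn <- qq_normalize(rpm)
    per_snp <- list()
    for (i in seq_len(nrow(sim$catalogue))) {
      bid <- snp_block[i]
      if (is.na(bid)) next
      widx <- which(windows$parent_block == bid)
      if (!length(widx)) next
      res <- scan_association(
        qqn[widx, , drop = FALSE],
        co$genotypes[sim$catalogue$rsid[i], ],
        co$meta, cohort = cname, engine = engines[[cname]],
        snp_rsid = sim$catalogue$rsid[i])
      per_snp[[length(per_snp) + 1L]] <- res
    }
    all_res <- do.call(rbind, per_snp)
    if (cname == "1DISC")
      n_tests <- sum(all_res$status == "tested")
    results[[cname]] <- aggregate_multi_snp(all_res)
  }

  threshold <- bonferroni_threshold(alpha, n_tests)
  cons <- consensus_windows(results, threshold)

  kept_windows <- apply_blacklist(windows, sim$blacklist)
  cons$blacklisted <- !(cons$window_id %in% kept_windows$window_id)
  passing_ids <- cons$window_id[cons$passes & !cons$blacklisted]

  pass_gr <- windows[match(passing_ids, windows$window_id)]
  if (length(pass_gr)) {
    ci <- match(passing_ids, cons$window_id)
    pass_gr$direction <- cons$direction[ci]
    pass_gr$p_max <- cons$p_max[ci]
    pass_gr$p_disc <- cons[ci, "p_1DISC"]
  }
  peaks <- merge_windows(pass_gr, max_gap = max_gap)
  if (length(peaks) && !is.null(sim$variants))
    peaks <- classify_peaks(peaks, sim$variants)
  summ <- peak_summary(peaks, sim$blocks)

  recovery <- NULL
  if (!is.null(sim$truth) && nrow(sim$truth)) {
    truth_gr <- GenomicRanges::GRanges(
      sim$truth$chrom, IRanges::IRanges(start = sim$truth$start + 1L,
                                        end = sim$truth$end))
    recovery <- sim$truth
    recovery$in_peak <- IRanges::overlapsAny(truth_gr, peaks)
  }
  structure(list(threshold = threshold, n_tests = n_tests,
                 results = results, consensus = cons, peaks = peaks,
                 summary = summ, recovery = recovery),
            class = "hsm_scan")
}
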