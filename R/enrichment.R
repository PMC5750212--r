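#' Contingency table of window-track overlap
#'
#' Counts background windows by (inside target set) x (hitting the track),
#' where "hitting" means the track covers at least `min_fraction` of the
#' window (bedtools `-f` on the window side, inclusive). The background is
#' the non-overlapping window tiling minus blacklist; the target set (e.g.
#' windows inside HSM peaks) must be a subset of the background universe.
#'
#' @param target GRanges of target windows, or a logical vector aligned
#'   with `background`.
#' @param track GRanges annotation track.
#' @param background GRanges of background windows.
#' @param min_fraction minimum covered window fraction (default 0.1).
#' @return list of class `"hsm_table"`: a (target, hit), b (target, miss),
#'   c (rest, hit), d (rest, miss), plus `degenerate` flag when a margin
#'   is empty.
#' @export
windowed_overlap_counts <- function(target, track, background,
                                    min_fraction = 0.1) {
  if (length(background) == 0L) stop("empty background")
  if (is.logical(target)) {
    in_target <- target
    if (length(in_target) != length(background))
      stop("logical target must align with background")
  } else {
    in_target <- IRanges::overlapsAny(background, target)
  }
  hit <- covered_fraction(background, track) >= min_fraction
  a <- sum(in_target & hit); b <- sum(in_target & !hit)
  cc <- sum(!in_target & hit); d <- sum(!in_target & !hit)
  structure(list(a = a, b = b, c = cc, d = d,
                 degenerate = (a + b == 0L) || (cc + d == 0L) ||
                   (a + cc == 0L) || (b + d == 0L)),
            class = "hsm_table")
}

covered_fraction <- function(windows, track) {
  track <- GenomicRanges::reduce(track)
  frac <- rep(0, length(windows))
  ov <- GenomicRanges::findOverlaps(windows, track)
  if (length(ov)) {
    inter_w <- GenomicRanges::width(IRanges::pintersect(
      windows[S4Vectors::queryHits(ov)], track[S4Vectors::subjectHits(ov)]))
    cov_bp <- tapply(inter_w, factor(S4Vectors::queryHits(ov),
                                     levels = seq_along(windows)), sum)
    cov_bp <- as.numeric(cov_bp); cov_bp[is.na(cov_bp)] <- 0
    frac <- cov_bp / GenomicRanges::width(windows)
  }
  frac
}

#' Odds ratio, Fisher's exact p and Woolf confidence interval
#'
#' The odds ratio is the sample OR `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe 0.5 correction is applied to the OR and its interval
#' only - the exact test always uses the raw counts. The two-sided p-value
#' comes from [stats::fisher.test()] (exact hypergeometric enumeration).
#'
#' @param table an `"hsm_table"` from [windowed_overlap_counts()], or the
#'   count `a` with `b`, `c`, `d` supplied separately.
#' @param b,c,d cell counts when `table` is given as a scalar `a`.
#' @return list: a, b, c, d, odds_ratio, ci95 (length-2 vector),
#'   fisher_p, corrected (TRUE when the 0.5 correction was used).
#' @export
fisher_or <- function(table, b = NULL, c = NULL, d = NULL) {
  if (inherits(table, "hsm_table")) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    a <- table
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) stop("cell counts must be >= 0")
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  list(a = a, b = b, c = c, d = d, odds_ratio = or, ci95 = ci,
       fisher_p = p, corrected = corrected)
}

#' Odds ratio from two proportions
#'
#' Reproduces density-derived odds ratios: `(p1/(1-p1)) / (p2/(1-p2))`.
#'
#' @param p1,p2 proportions in (0, 1).
#' @return the odds ratio.
#' @export
odds_ratio_from_props <- function(p1, p2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Base-pair fold enrichment of peaks across a panel of tracks
#'
#' For each track, the fold enrichment is the proportion of peak base pairs
#' inside the track divided by the proportion of background base pairs
#' inside the track, with a nominal chi-squared p-value on the 2x2 table of
#' base-pair counts. A Bonferroni-adjusted p column across the panel is
#' emitted alongside the nominal values.
#'
#' @param peaks GRanges of peaks.
#' @param tracks named list of GRanges tracks (e.g. per-tissue DHS sets).
#' @param background GRanges background regions.
#' @return data.frame per track: track, peak_bp, peak_bp_in, bg_bp,
#'   bg_bp_in, fold, log2_fold, chisq_p, bonferroni_p; attribute
#'   `n_nominal` counts tracks with chisq_p < 0.05.
#' @export
tissue_panel_fold <- function(peaks, tracks, background) {
  stopifnot(length(tracks) >= 1L)
  if (is.null(names(tracks)))
    names(tracks) <- paste0("track_", seq_along(tracks))
  pk <- GenomicRanges::reduce(peaks)
  bg <- GenomicRanges::reduce(background)
  peak_bp <- sum(as.numeric(GenomicRanges::width(pk)))
  bg_bp <- sum(as.numeric(GenomicRanges::width(bg)))
  rows <- lapply(names(tracks), function(nm) {
    tr <- GenomicRanges::reduce(tracks[[nm]])
    p_in <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(pk, tr))))
    b_in <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(bg, tr))))
    fold <- if (b_in == 0) NA_real_ else (p_in / peak_bp) / (b_in / bg_bp)
    pval <- if (b_in == 0) NA_real_ else suppressWarnings(
      stats::chisq.test(matrix(c(p_in, peak_bp - p_in,
                                 b_in, bg_bp - b_in),
                               nrow = 2, byrow = TRUE),
                        correct = FALSE)$p.value)
    data.frame(track = nm, peak_bp = peak_bp, peak_bp_in = p_in,
               bg_bp = bg_bp, bg_bp_in = b_in, fold = fold,
               log2_fold = log2(fold), chisq_p = pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- pmin(1, out$chisq_p * nrow(out))
  attr(out, "n_nominal") <- sum(out$chisq_p < 0.05, na.rm = TRUE)
  out
}

#' Overlap of a SNP set with HSM peaks
#'
#' SNP positions are treated as points; a SNP on a peak boundary base is
#' inside the peak. The window-level contingency table compares background
#' windows inside peaks against the rest for presence of at least one SNP,
#' and per-SNP annotations (in_peak, is_cpg_snp when supplied) support
#' composition summaries such as the fraction of peak-overlapping SNPs that
#' are CpG-SNPs.
#'
#' @param peaks GRanges of peaks.
#' @param snps GRanges of width-1 SNP positions; optional metadata column
#'   `is_cpg_snp`.
#' @param background GRanges of background windows.
#' @return list: n_snps, n_in_peaks, table (`"hsm_table"`), test (from
#'   [fisher_or()]), snps (annotated GRanges), frac_cpg_in_peaks.
#' @export
snp_set_overlap <- function(peaks, snps, background) {
  in_peak <- IRanges::overlapsAny(snps, peaks)
  win_in_peak <- IRanges::overlapsAny(background, peaks)
  win_has_snp <- IRanges::overlapsAny(background, snps)
  tab <- structure(list(
    a = sum(win_in_peak & win_has_snp),
    b = sum(win_in_peak & !win_has_snp),
    c = sum(!win_in_peak & win_has_snp),
    d = sum(!win_in_peak & !win_has_snp),
    degenerate = FALSE), class = "hsm_table")
  snps$in_peak <- in_peak
  frac_cpg <- if (!is.null(snps$is_cpg_snp) && any(in_peak))
    mean(snps$is_cpg_snp[in_peak], na.rm = TRUE) else NA_real_
  list(n_snps = length(snps), n_in_peaks = sum(in_peak), table = tab,
       test = fisher_or(tab), snps = snps, frac_cpg_in_peaks = frac_cpg)
}
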