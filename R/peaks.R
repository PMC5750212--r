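#' Tri-cohort significance-and-direction consensus
#'
#' A window passes only if it was tested in all three cohorts, its p-value
#' is below `threshold` in each, and the direction of effect agrees across
#' all three. Failures carry a reason code: `missing` (not tested
#' everywhere), `p_fail_<cohort>` (first cohort failing the threshold) or
#' `direction_conflict`.
#'
#' @param results named list of three aggregated result data.frames (from
#'   [aggregate_multi_snp()] or [scan_association()]), with columns
#'   window_id, p_value, direction.
#' @param threshold significance threshold (e.g. [bonferroni_threshold()]).
#' @return data.frame: window_id, p_<cohort>, dir_<cohort>, p_max (largest
#'   of the three p-values), direction, passes, reason.
#' @export
consensus_windows <- function(results, threshold) {
  stopifnot(length(results) == 3L)
  if (is.null(names(results))) names(results) <- c("1DISC", "2FOLL", "3REPL")
  ids <- unique(unlist(lapply(results, function(d) d$window_id)))
  out <- data.frame(window_id = ids, stringsAsFactors = FALSE)
  for (nm in names(results)) {
    d <- results[[nm]]
    i <- match(ids, d$window_id)
    out[[paste0("p_", nm)]] <- d$p_value[i]
    out[[paste0("dir_", nm)]] <- d$direction[i]
  }
  pmat <- as.matrix(out[, paste0("p_", names(results))])
  dmat <- as.matrix(out[, paste0("dir_", names(results))])
  out$p_max <- apply(pmat, 1L, max)
  out$direction <- dmat[, 1]
  tested_all <- stats::complete.cases(pmat) & stats::complete.cases(dmat)
  sig_all <- tested_all & apply(pmat < threshold, 1L, all)
  dir_ok <- tested_all &
    apply(dmat, 1L, function(d) length(unique(d)) == 1L && all(d != 0))
  out$passes <- sig_all & dir_ok

  reason <- rep(NA_character_, nrow(out))
  reason[!tested_all] <- "missing"
  for (nm in rev(names(results))) {
    bad <- tested_all & !is.na(pmat[, paste0("p_", nm)]) &
      pmat[, paste0("p_", nm)] >= threshold
    reason[bad] <- paste0("p_fail_", nm)
  }
  reason[tested_all & sig_all & !dir_ok] <- "direction_conflict"
  reason[out$passes] <- NA_character_
  out$reason <- reason
  out
}

#' Merge consensus windows into HSM peaks
#'
#' Windows whose intervals overlap or touch (gap at most `max_gap` bp) are
#' merged into one peak. A run of windows is split at a change of direction:
#' peaks are directionally homogeneous, and when opposite-sign windows
#' overlap, the later peak is clipped to start after the earlier one ends so
#' that peaks stay pairwise disjoint.
#'
#' @param windows GRanges of passing windows, with metadata columns
#'   `direction` (+1/-1), `p_max` (tri-cohort maximum p) and optionally
#'   `p_disc` (discovery-cohort p).
#' @param max_gap largest allowed gap in bp between merged windows
#'   (default 0 = overlapping or bookended).
#' @return GRanges of peaks with `peak_id`, `n_windows`, `direction`,
#'   `min_p` (minimum over members of `p_max`) and `p_disc_min`.
#' @export
merge_windows <- function(windows, max_gap = 0L) {
  if (length(windows) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$peak_id <- character(); gr$n_windows <- integer()
    gr$direction <- numeric(); gr$min_p <- numeric()
    gr$p_disc_min <- numeric()
    return(gr)
  }
  if (is.null(windows$direction)) windows$direction <- rep(1, length(windows))
  if (is.null(windows$p_max)) windows$p_max <- rep(NA_real_, length(windows))
  if (is.null(windows$p_disc)) windows$p_disc <- rep(NA_real_, length(windows))
  o <- order(as.character(GenomicRanges::seqnames(windows)),
             GenomicRanges::start(windows))
  w <- windows[o]

  chrom <- as.character(GenomicRanges::seqnames(w))
  st <- GenomicRanges::start(w); en <- GenomicRanges::end(w)
  dir <- w$direction
  grp <- integer(length(w)); grp[1] <- 1L
  if (length(w) > 1L) for (i in 2:length(w)) {
    same_run <- chrom[i] == chrom[i - 1L] &&
      st[i] <= max(en[seq_len(i - 1L)][grp[seq_len(i - 1L)] == grp[i - 1L]]) +
        max_gap + 1L &&
      dir[i] == dir[i - 1L]
    grp[i] <- if (same_run) grp[i - 1L] else grp[i - 1L] + 1L
  }

  parts <- split(seq_along(w), grp)
  peaks <- lapply(parts, function(idx) {
    data.frame(chrom = chrom[idx[1]], start = min(st[idx]),
               end = max(en[idx]), n_windows = length(idx),
               direction = dir[idx[1]],
               min_p = suppressWarnings(min(w$p_max[idx], na.rm = TRUE)),
               p_disc_min = suppressWarnings(min(w$p_disc[idx],
                                                 na.rm = TRUE)))
  })
  pk <- do.call(rbind, peaks)
  pk$min_p[!is.finite(pk$min_p)] <- NA_real_
  pk$p_disc_min[!is.finite(pk$p_disc_min)] <- NA_real_
  # clip overlaps between adjacent opposite-direction peaks
  if (nrow(pk) > 1L) for (i in 2:nrow(pk)) {
    if (pk$chrom[i] == pk$chrom[i - 1L] && pk$start[i] <= pk$end[i - 1L])
      pk$start[i] <- pk$end[i - 1L] + 1L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = pk$chrom,
    ranges = IRanges::IRanges(start = pk$start, end = pk$end),
    peak_id = sprintf("peak_%04d", seq_len(nrow(pk))),
    n_windows = pk$n_windows, direction = pk$direction,
    min_p = pk$min_p, p_disc_min = pk$p_disc_min
  )
  names(gr) <- gr$peak_id
  gr
}

#' Summarize a set of HSM peaks
#'
#' @param peaks GRanges of peaks.
#' @param blocks optional GRanges of LD blocks, for per-block statistics.
#' @return one-row data.frame: n_peaks, span_bp, mean_length_bp,
#'   median_length_bp, and (when blocks are given) peaks_per_block and
#'   frac_blocks_with_peak.
#' @export
peak_summary <- function(peaks, blocks = NULL) {
  n <- length(peaks)
  out <- data.frame(
    n_peaks = n,
    span_bp = if (n) sum(GenomicRanges::width(peaks)) else 0,
    mean_length_bp = if (n) mean(GenomicRanges::width(peaks)) else NA_real_,
    median_length_bp = if (n) stats::median(GenomicRanges::width(peaks))
                       else NA_real_
  )
  if (!is.null(blocks) && length(blocks)) {
    hits <- IRanges::overlapsAny(blocks, peaks)
    out$peaks_per_block <- n / length(blocks)
    out$frac_blocks_with_peak <- mean(hits)
  }
  out
}
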