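#' Tile fixed-size sliding windows over regions
#'
#' Produces the MeDIP analysis grid: `size` bp windows advanced by `slide`
#' bp within each region. With `slide == size` this is the non-overlapping
#' background tiling used for enrichment. Terminal partial windows are
#' dropped, never padded; a region shorter than `size` yields no windows.
#'
#' @param regions GRanges of regions (e.g. LD blocks). A `block_id` metadata
#'   column, or names, is propagated to `parent_block`.
#' @param size window length in bp (default 500).
#' @param slide step between window starts in bp (default 250); `size` must
#'   be a multiple of `slide`.
#' @return GRanges of windows with metadata columns `window_id`
#'   (BED-style `chrom:start0-end` string) and `parent_block`; sorted by
#'   (chrom, start), deduplicated on `window_id`.
#' @export
tile_windows <- function(regions, size = 500L, slide = 250L) {
  size <- as.integer(size); slide <- as.integer(slide)
  stopifnot(size > 0L, slide > 0L)
  if (size %% slide != 0L)
    stop("window size must be a multiple of the slide")
  parent <- if (!is.null(regions$block_id)) regions$block_id
            else if (!is.null(names(regions))) names(regions)
            else rep(NA_character_, length(regions))
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    w <- GenomicRanges::width(regions)[i]
    if (w < size) next
    s0 <- GenomicRanges::start(regions)[i]
    starts <- seq.int(s0, s0 + w - size, by = slide)
    out[[i]] <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(regions)[i]),
      ranges = IRanges::IRanges(start = starts, width = size),
      parent_block = parent[i]
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    gr$window_id <- character()
    gr$parent_block <- character()
    return(gr)
  }
  gr <- do.call(c, out)
  gr$window_id <- window_ids(gr)
  gr <- gr[!duplicated(gr$window_id)]
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  names(gr) <- gr$window_id
  gr
}

window_ids <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Reads-per-million normalization of window counts
#'
#' @param counts numeric matrix, windows in rows, samples in columns.
#' @param library_sizes numeric vector of total read counts per sample,
#'   aligned with the columns of `counts`; all entries must be positive.
#' @return matrix of RPM values with attribute `scale = "RPM"`.
#' @export
rpm_normalize <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  if (length(library_sizes) != ncol(counts))
    stop("one library size per sample required")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  rpm <- sweep(counts, 2L, library_sizes, function(x, ls) x * 1e6 / ls)
  attr(rpm, "scale") <- "RPM"
  rpm
}

#' Rank-based inverse-normal ("qqN") transform per window
#'
#' Each window's scores are transformed across samples: average ranks `r`
#' map to standard-normal quantiles at offsets `(r - 0.5) / n`, so tied
#' values receive the quantile of their mean rank position. A constant
#' window transforms to all zeros and is flagged low-variance.
#'
#' @param mat numeric matrix, windows in rows, samples in columns; at least
#'   3 samples.
#' @return matrix of transformed values (attributes `scale = "qqN"` and
#'   `low_variance`, the row names of flagged windows).
#' @export
qq_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) stop("qq_normalize needs at least 3 samples")
  if (anyNA(mat)) stop("missing values in score matrix")
  n <- ncol(mat)
  flagged <- character()
  out <- mat
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    if (max(x) == min(x)) {
      out[i, ] <- 0
      flagged <- c(flagged, rownames(mat)[i] %||% as.character(i))
    } else {
      r <- rank(x, ties.method = "average")
      out[i, ] <- stats::qnorm((r - 0.5) / n)
    }
  }
  attr(out, "scale") <- "qqN"
  attr(out, "low_variance") <- flagged
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove windows overlapping blacklist regions
#'
#' Applied after association testing and before peak calling; any overlap
#' (1 bp or more) disqualifies a window.
#'
#' @param windows GRanges of windows.
#' @param blacklist GRanges of masked regions.
#' @return the retained windows; the number removed is reported via
#'   `message()`, and an empty result raises a warning.
#' @export
apply_blacklist <- function(windows, blacklist) {
  if (length(blacklist) == 0L) return(windows)
  hit <- IRanges::overlapsAny(windows, blacklist)
  message(sum(hit), " windows removed by blacklist")
  kept <- windows[!hit]
  if (length(kept) == 0L && length(windows) > 0L)
    warning("blacklist removed every window")
  kept
}
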