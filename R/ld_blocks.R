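#' Read a genetic map TSV
#'
#' Expects a tab-separated file with columns `chrom`, `pos` (1-based bp) and
#' `rate` (recombination rate in cM/Mb). Positions must be strictly
#' increasing within each chromosome.
#'
#' @param path file path.
#' @return data.frame with columns chrom, pos, rate.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "rate")
  if (!all(need %in% names(map)))
    stop("genetic map must have columns: ", paste(need, collapse = ", "))
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  validate_genetic_map(map)
  map
}

validate_genetic_map <- function(map) {
  if (any(map$rate < 0)) stop("negative recombination rate in map")
  bad <- tapply(map$pos, map$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(bad)))
    stop("map positions must be strictly increasing within chromosome")
  invisible(map)
}

#' Read a GWAS catalogue TSV
#'
#' Expects columns `rsid`, `chrom`, `pos` (1-based), `trait`, `p`. Rows with
#' association p-values at or above `max_p` are dropped, mirroring the
#' catalogue convention of retaining genome-wide results only.
#'
#' @param path file path.
#' @param max_p retain rows with p strictly below this (default 1e-7).
#' @return data.frame of catalogue rows.
#' @export
read_gwas_catalogue <- function(path, max_p = 1e-7) {
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "trait", "p")
  if (!all(need %in% names(cat_df)))
    stop("catalogue must have columns: ", paste(need, collapse = ", "))
  cat_df[cat_df$p < max_p, , drop = FALSE]
}

#' Build recombination-bounded LD blocks around GWAS SNPs
#'
#' Genetic-map positions with recombination rate at or above `rate_threshold`
#' (cM/Mb) act as block boundary walls. Each SNP's block runs from the
#' nearest wall strictly upstream (that base pair excluded) to the nearest
#' wall at or downstream (that base pair included); with no flanking wall the
#' block extends to the mapped ends of the chromosome. SNPs whose block
#' intervals coincide are merged into a single block. SNPs on chromosomes
#' absent from the map are recorded as unplaced, not dropped silently.
#'
#' @param map data.frame with chrom, pos, rate (see [read_genetic_map()]).
#' @param snps data.frame with rsid, chrom, pos (1-based) and optionally
#'   trait, p.
#' @param rate_threshold boundary recombination rate, cM/Mb (default 10).
#' @return list with elements `blocks` (GRanges, 1-based closed, with
#'   `block_id` and `n_snps`), `assignments` (data.frame rsid, chrom, pos,
#'   block_id; one row per unique SNP) and `unplaced` (data.frame rsid,
#'   reason).
#' @export
build_blocks <- function(map, snps, rate_threshold = 10) {
  stopifnot(rate_threshold > 0)
  validate_genetic_map(map)
  usnps <- unique(snps[, c("rsid", "chrom", "pos")])
  if (anyDuplicated(usnps$rsid))
    stop("rsid maps to more than one position")

  placed <- vector("list", nrow(usnps))
  unplaced <- list()
  map_by_chrom <- split(map, map$chrom)
  for (i in seq_len(nrow(usnps))) {
    chrom <- usnps$chrom[i]
    pos <- usnps$pos[i]
    m <- map_by_chrom[[chrom]]
    if (is.null(m)) {
      unplaced[[length(unplaced) + 1L]] <-
        data.frame(rsid = usnps$rsid[i], reason = "chrom_not_in_map")
      next
    }
    walls <- m$pos[m$rate >= rate_threshold]
    up <- walls[walls < pos]
    down <- walls[walls >= pos]
    # (upstream wall, downstream wall] in bp; map ends when no wall flanks
    start1 <- if (length(up)) max(up) + 1L else min(m$pos)
    end1 <- if (length(down)) min(down) else max(m$pos)
    placed[[i]] <- data.frame(
      rsid = usnps$rsid[i], chrom = chrom, pos = pos,
      start = start1, end = end1
    )
  }
  placed <- do.call(rbind, placed)
  unplaced <- if (length(unplaced)) do.call(rbind, unplaced) else
    data.frame(rsid = character(), reason = character())

  if (is.null(placed) || nrow(placed) == 0L) {
    return(list(
      blocks = GenomicRanges::GRanges(),
      assignments = data.frame(rsid = character(), chrom = character(),
                               pos = integer(), block_id = character()),
      unplaced = unplaced
    ))
  }

  placed$block_id <- sprintf("%s:%d-%d", placed$chrom, placed$start - 1L,
                             placed$end)
  blk <- placed[!duplicated(placed$block_id),
                c("chrom", "start", "end", "block_id")]
  blk <- blk[order(blk$chrom, blk$start), , drop = FALSE]
  blocks <- GenomicRanges::GRanges(
    seqnames = blk$chrom,
    ranges = IRanges::IRanges(start = blk$start, end = blk$end),
    block_id = blk$block_id,
    n_snps = as.integer(table(placed$block_id)[blk$block_id])
  )
  names(blocks) <- blocks$block_id
  list(
    blocks = blocks,
    assignments = placed[, c("rsid", "chrom", "pos", "block_id")],
    unplaced = unplaced
  )
}

#' Fraction of the genome covered by LD blocks
#'
#' @param blocks GRanges of blocks.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @return fraction in \[0, 1\].
#' @export
genome_fraction <- function(blocks, chrom_sizes) {
  if (length(blocks) == 0L) return(0)
  used <- unique(as.character(GenomicRanges::seqnames(blocks)))
  if (!all(used %in% names(chrom_sizes)))
    stop("chrom_sizes missing chromosomes: ",
         paste(setdiff(used, names(chrom_sizes)), collapse = ", "))
  covered <- sum(as.numeric(
    GenomicRanges::width(GenomicRanges::reduce(blocks))))
  covered / sum(as.numeric(chrom_sizes))
}

#' Collapse catalogue rows into unique SNP-by-block analyses
#'
#' A SNP reported for several traits is analysed once; SNPs co-locating in a
#' shared block remain separate analyses.
#'
#' @param catalogue data.frame of catalogue rows (rsid, trait, ...).
#' @param assignments data.frame from [build_blocks()].
#' @return data.frame with one row per (rsid, block_id) analysis.
#' @export
dedupe_snp_analyses <- function(catalogue, assignments) {
  keep <- assignments[assignments$rsid %in% unique(catalogue$rsid),
                      c("rsid", "block_id")]
  unique(keep)
}
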