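#' Classify a SNP as a CpG-SNP
#'
#' A SNP is a CpG-SNP when its allelic variation creates or abolishes a CpG
#' dinucleotide in the reference context: among the alleles there exist two,
#' a and b, such that exactly one of them forms CG with the 3' flanking base
#' (allele C with flank3 G) or with the 5' flanking base (flank5 C with
#' allele G). Evaluated on the forward strand of the supplied context; the
#' classification is reverse-complement invariant. Any ambiguous base (not
#' A/C/G/T) in the flanks yields `NA` ("unknown"), to be excluded from
#' denominators.
#'
#' @param alleles character vector of single-base alleles (length >= 2).
#' @param flank5 base immediately 5' of the SNP.
#' @param flank3 base immediately 3' of the SNP.
#' @return list with `is_cpg_snp` (TRUE/FALSE/NA), `side` ("5prime",
#'   "3prime", "both" or NA) and `cpg_alleles` (alleles that form a CpG).
#' @export
classify_cpg_snp <- function(alleles, flank5, flank3) {
  bases <- c("A", "C", "G", "T")
  alleles <- toupper(alleles); flank5 <- toupper(flank5)
  flank3 <- toupper(flank3)
  if (length(alleles) < 2L) stop("need at least two alleles")
  if (!(flank5 %in% bases) || !(flank3 %in% bases) ||
      !all(alleles %in% bases))
    return(list(is_cpg_snp = NA, side = NA_character_,
                cpg_alleles = character()))
  on3 <- alleles == "C" & flank3 == "G"
  on5 <- flank5 == "C" & alleles == "G"
  status <- on3 | on5
  is_cpg <- any(status) && any(!status)
  side <- if (!is_cpg) NA_character_
          else if (any(on3) && any(on5)) "both"
          else if (any(on3)) "3prime" else "5prime"
  list(is_cpg_snp = is_cpg, side = side,
       cpg_alleles = alleles[status])
}

#' Classify SNP contexts in bulk
#'
#' @param contexts data.frame with columns `rsid`, `alleles` (comma- or
#'   slash-separated bases), `flank5`, `flank3`.
#' @return the input with added logical column `is_cpg_snp` (NA where the
#'   context is ambiguous) and `cpg_side`.
#' @export
classify_cpg_snps <- function(contexts) {
  res <- lapply(seq_len(nrow(contexts)), function(i) {
    al <- strsplit(gsub("/", ",", contexts$alleles[i]), ",")[[1]]
    classify_cpg_snp(al, contexts$flank5[i], contexts$flank3[i])
  })
  contexts$is_cpg_snp <- vapply(res, function(r) r$is_cpg_snp, logical(1))
  contexts$cpg_side <- vapply(res, function(r) r$side, character(1))
  contexts
}

#' Label peaks by overlapping variant classes
#'
#' A variant class counts when its intervals cover at least `min_fraction`
#' of the peak's length (bedtools `-f` semantics, measured on the peak).
#' Zero qualifying classes gives "Other"; one gives that class, with eSTR
#' taking precedence over plain STR (the eSTR set is a subset of the STR
#' set); two or more distinct classes among CNV, Indel and STR-or-eSTR give
#' "Multiple".
#'
#' @param peaks GRanges of peaks (metadata `peak_id` used if present).
#' @param variants named list of GRanges, names among "CNV", "Indel",
#'   "STR", "eSTR".
#' @param min_fraction minimum covered fraction of the peak (default 0.1,
#'   inclusive).
#' @return the peaks GRanges with an added `variant_class` metadata column.
#' @export
classify_peaks <- function(peaks, variants, min_fraction = 0.1) {
  known <- c("CNV", "Indel", "STR", "eSTR")
  variants <- variants[intersect(names(variants), known)]
  hit <- matrix(FALSE, nrow = length(peaks), ncol = length(known),
                dimnames = list(NULL, known))
  for (cls in names(variants)) {
    v <- GenomicRanges::reduce(variants[[cls]])
    if (length(v) == 0L) next
    cov_bp <- rep(0, length(peaks))
    ov <- GenomicRanges::findOverlaps(peaks, v)
    if (length(ov)) {
      inter_w <- GenomicRanges::width(IRanges::pintersect(
        peaks[S4Vectors::queryHits(ov)], v[S4Vectors::subjectHits(ov)]))
      cov_bp <- as.numeric(tapply(inter_w, factor(S4Vectors::queryHits(ov),
                                                  levels = seq_along(peaks)),
                                  sum))
      cov_bp[is.na(cov_bp)] <- 0
    }
    hit[, cls] <- cov_bp / GenomicRanges::width(peaks) >= min_fraction
  }
  label <- vapply(seq_len(length(peaks)), function(i) {
    h <- hit[i, ]
    str_like <- h["STR"] || h["eSTR"]
    classes <- c(CNV = unname(h["CNV"]), Indel = unname(h["Indel"]),
                 STRish = str_like)
    n <- sum(classes)
    if (n == 0L) "Other"
    else if (n >= 2L) "Multiple"
    else if (classes["STRish"]) (if (h["eSTR"]) "eSTR" else "STR")
    else names(classes)[classes]
  }, character(1))
  peaks$variant_class <- label
  peaks
}

#' CpG and CpG-SNP sequence densities
#'
#' CpG density is expressed as percent of sequence occupied by CpG
#' dinucleotides (50 CpGs in 100 bp = 100 percent), i.e.
#' `2 * count / length * 100`; a per-kb rate (`count / length * 1000`) is
#' reported alongside. CpG-SNP density uses the same dinucleotide
#' convention for a supplied count of CpG-SNPs in the sequence set.
#'
#' @param seqs character vector or Biostrings::DNAStringSet of sequences.
#' @param n_cpg_snp total CpG-SNPs within the sequence set (default 0).
#' @return one-row data.frame: length_bp, n_cpg, cpg_density_pct,
#'   cpg_per_kb, n_cpg_snp, cpg_snp_density_pct.
#' @export
sequence_densities <- function(seqs, n_cpg_snp = 0) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  total_len <- sum(Biostrings::width(seqs))
  if (total_len == 0L) stop("zero-length sequence set")
  n_cpg <- sum(Biostrings::vcountPattern("CG", seqs))
  data.frame(
    length_bp = total_len,
    n_cpg = n_cpg,
    cpg_density_pct = 2 * n_cpg / total_len * 100,
    cpg_per_kb = n_cpg / total_len * 1000,
    n_cpg_snp = n_cpg_snp,
    cpg_snp_density_pct = 2 * n_cpg_snp / total_len * 100
  )
}
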