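# Independent oracles used across the suite. These never call the package
# code paths they are checking.

# Normal-equations least squares: RSS of y ~ X (X includes intercept).
oracle_rss <- function(y, X) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

# Matched-likelihood LRT p for adding column g to design X: RSS via normal
# equations, F -> LRT = n log(1 + F df1/df2) -> chi-squared(1) upper tail.
oracle_lrt_p <- function(y, g, X) {
  n <- length(y)
  rss0 <- oracle_rss(y, X)
  rss1 <- oracle_rss(y, cbind(X, g))
  k <- ncol(X) + 1L
  f_stat <- (rss0 - rss1) / (rss1 / (n - k))
  lrt <- n * log(1 + f_stat / (n - k))
  list(lrt = lrt, p = pchisq(lrt, df = 1, lower.tail = FALSE),
       f_p = pf(f_stat, 1, n - k, lower.tail = FALSE))
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# the support of cell a given fixed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Measure of the union of 1-based closed intervals by brute-force bp set.
oracle_union_bp <- function(starts, ends) {
  length(unique(unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))))
}

# CpG-SNP classification by brute-force enumeration of the dinucleotide
# set each allele produces in its context.
oracle_cpg_snp <- function(alleles, flank5, flank3) {
  has_cpg <- vapply(alleles, function(a) {
    s <- paste0(flank5, a, flank3)
    grepl("CG", s, fixed = TRUE)
  }, logical(1))
  any(has_cpg) && any(!has_cpg)
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# Brute-force window tiling: every start position s with s %% slide aligned
# to the region start and [s, s + size) fully inside the region.
oracle_tile_starts <- function(region_start, region_end, size, slide) {
  # 1-based closed region
  starts <- seq.int(region_start, region_end, by = slide)
  starts[starts + size - 1L <= region_end]
}

# Array covariate design assembled directly for the reduction oracle.
build_design_oracle <- function(meta) {
  model.matrix(~ age + smoking + beadchip + beadchip_pos + granulocytes +
                 monocytes_arr + cd8t, data = meta)
}

make_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    age = runif(n, 20, 80),
    sex = sample(c("F", "M"), n, replace = TRUE),
    lymphocytes = runif(n, 0.15, 0.45),
    monocytes = runif(n, 0.02, 0.12),
    neutrophils = runif(n, 0.35, 0.7),
    eosinophils = runif(n, 0, 0.08),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE),
    batch = sample(paste0("b", 1:3), n, replace = TRUE),
    family_id = sprintf("F%03d", seq_len(n)),
    individual_id = sprintf("I%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}
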