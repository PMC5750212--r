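#' Covariate sets used by each cohort's association model
#'
#' Discovery and follow-up cohorts adjust for age, the four blood cell
#' fractions, smoking status and batch; the replication cohort adds sex and
#' drops the blood and smoking covariates.
#'
#' @param cohort one of "1DISC", "2FOLL", "3REPL", or "array" for the
#'   methylation-array analysis (age, smoking, beadchip, beadchip position,
#'   granulocytes, monocytes, CD8+ T cells).
#' @return character vector of covariate column names.
#' @export
hsm_covariates <- function(cohort = c("1DISC", "2FOLL", "3REPL", "array")) {
  cohort <- match.arg(cohort)
  switch(cohort,
    "1DISC" = c("age", "lymphocytes", "monocytes", "neutrophils",
                "eosinophils", "smoking", "batch"),
    "2FOLL" = c("age", "lymphocytes", "monocytes", "neutrophils",
                "eosinophils", "smoking", "batch"),
    "3REPL" = c("age", "sex", "batch"),
    "array" = c("age", "smoking", "beadchip", "beadchip_pos",
                "granulocytes", "monocytes_arr", "cd8t")
  )
}

assoc_result <- function(window_id = NA_character_, snp_rsid = NA_character_,
                         cohort = NA_character_, beta = NA_real_,
                         lrt_stat = NA_real_, p_value = NA_real_,
                         n_used = NA_integer_, status = "tested",
                         note = NA_character_) {
  data.frame(window_id = window_id, snp_rsid = snp_rsid, cohort = cohort,
             beta = beta, lrt_stat = lrt_stat, p_value = p_value,
             n_used = as.integer(n_used), status = status, note = note,
             stringsAsFactors = FALSE)
}

# Assemble the model frame: score, genotype, requested covariates.
# Listwise deletion of incomplete rows; factors re-dropped after subsetting.
assoc_frame <- function(score, genotype, meta, covariates) {
  covariates <- intersect(covariates, names(meta))
  df <- data.frame(score = as.numeric(score),
                   genotype = as.numeric(genotype))
  for (cv in covariates) df[[cv]] <- meta[[cv]]
  keep <- stats::complete.cases(df)
  df <- droplevels(df[keep, , drop = FALSE])
  # drop covariates that became constant (single level / zero variance)
  usable <- vapply(covariates, function(cv) {
    x <- df[[cv]]
    if (is.numeric(x)) length(unique(x)) > 1L else nlevels(factor(x)) > 1L
  }, logical(1))
  attr(df, "covariates") <- covariates[usable]
  attr(df, "kept") <- keep
  df
}

assoc_status <- function(df) {
  if (nrow(df) < 3L) return("skipped_constant")
  if (max(df$score) == min(df$score)) return("skipped_constant")
  if (length(unique(df$genotype)) < 2L) return("skipped_monomorphic")
  "tested"
}

#' Discovery-stage window association (covariate-adjusted linear model)
#'
#' Fits `score ~ allelic_count + covariates` and the null model without the
#' allelic count by ordinary least squares; the likelihood-ratio statistic
#' is `2 * (logLik(full) - logLik(null))` and its p-value comes from the
#' upper tail of a chi-squared distribution with 1 df.
#'
#' @param score numeric vector of normalized window scores.
#' @param genotype numeric allelic counts (0/1/2), additive coding.
#' @param meta data.frame of per-sample covariates.
#' @param covariates covariate column names (default the discovery set).
#' @param window_id,snp_rsid identifiers carried into the result.
#' @return one-row data.frame: window_id, snp_rsid, cohort, beta (score
#'   units per allele), lrt_stat, p_value, n_used, status, note.
#' @export
fit_discovery <- function(score, genotype, meta,
                          covariates = hsm_covariates("1DISC"),
                          window_id = NA_character_,
                          snp_rsid = NA_character_) {
  df <- assoc_frame(score, genotype, meta, covariates)
  status <- assoc_status(df)
  if (status != "tested")
    return(assoc_result(window_id, snp_rsid, "1DISC", status = status,
                        n_used = nrow(df)))
  covs <- attr(df, "covariates")
  rhs_null <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  full <- stats::lm(stats::as.formula(
    paste("score ~ genotype +", rhs_null)), data = df)
  null <- stats::lm(stats::as.formula(
    paste("score ~", rhs_null)), data = df)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                     as.numeric(stats::logLik(null))))
  assoc_result(window_id, snp_rsid, "1DISC",
               beta = unname(stats::coef(full)["genotype"]),
               lrt_stat = lrt,
               p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
               n_used = nrow(df), status = "tested")
}

#' Follow-up / replication window association (linear mixed model)
#'
#' Fixed effects as in [fit_discovery()] (for "3REPL" sex is added and the
#' blood/smoking covariates are dropped); random intercepts for family and,
#' when repeated measures exist, for individual nested within family. Both
#' the full and the null model are fitted by maximum likelihood (not REML)
#' with lme4, and compared by likelihood-ratio test against chi-squared
#' with 1 df.
#'
#' When no grouping factor has more than one observation the mixed model is
#' degenerate and the fit reduces exactly to ordinary least squares; this
#' function then takes the OLS path and flags `note = "ols_reduction"`.
#' A singular random-effect fit is refitted with a family-only intercept
#' and flagged `note = "singular_refit"`.
#'
#' @inheritParams fit_discovery
#' @param cohort "2FOLL" or "3REPL"; selects the default covariate set.
#' @param random "family_individual" (default) for nested intercepts or
#'   "family_only".
#' @return one-row data.frame as in [fit_discovery()].
#' @export
fit_mixed <- function(score, genotype, meta, cohort = c("2FOLL", "3REPL"),
                      covariates = NULL,
                      random = c("family_individual", "family_only"),
                      window_id = NA_character_, snp_rsid = NA_character_) {
  cohort <- match.arg(cohort)
  random <- match.arg(random)
  if (is.null(covariates)) covariates <- hsm_covariates(cohort)
  if (!all(c("family_id", "individual_id") %in% names(meta)))
    stop("meta must contain family_id and individual_id")

  df <- assoc_frame(score, genotype, meta, covariates)
  kept <- attr(df, "kept")
  df$family_id <- factor(meta$family_id[kept])
  df$individual_id <- factor(paste(meta$family_id, meta$individual_id,
                                   sep = ":")[kept])
  status <- assoc_status(df)
  if (status != "tested")
    return(assoc_result(window_id, snp_rsid, cohort, status = status,
                        n_used = nrow(df)))

  fam_sizes <- table(df$family_id)
  ind_sizes <- table(df$individual_id)
  note <- NA_character_

  if (max(fam_sizes) == 1L) {
    # all singleton families: random effects unidentifiable; exact OLS limit
    res <- fit_discovery(df$score, df$genotype, df, covariates,
                         window_id = window_id, snp_rsid = snp_rsid)
    res$cohort <- cohort
    res$note <- "ols_reduction"
    return(res)
  }

  re_terms <- "(1 | family_id)"
  if (random == "family_individual" && max(ind_sizes) > 1L)
    re_terms <- c(re_terms, "(1 | individual_id)")

  covs <- attr(df, "covariates")
  fe <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste("score ~ genotype +", fe, "+",
                                    paste(re_terms, collapse = " + ")))
  f_null <- stats::as.formula(paste("score ~", fe, "+",
                                    paste(re_terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit_pair <- function(ff, fn) {
    full <- lme4::lmer(ff, data = df, REML = FALSE, control = ctrl)
    null <- lme4::lmer(fn, data = df, REML = FALSE, control = ctrl)
    list(full = full, null = null)
  }
  fits <- tryCatch(fit_pair(f_full, f_null), error = function(e) e)
  if (inherits(fits, "error"))
    return(assoc_result(window_id, snp_rsid, cohort,
                        status = "failed_converge", n_used = nrow(df),
                        note = conditionMessage(fits)))
  if (length(re_terms) > 1L && lme4::isSingular(fits$full, tol = 1e-5)) {
    f_full2 <- stats::as.formula(paste("score ~ genotype +", fe,
                                       "+ (1 | family_id)"))
    f_null2 <- stats::as.formula(paste("score ~", fe, "+ (1 | family_id)"))
    refit <- tryCatch(fit_pair(f_full2, f_null2), error = function(e) NULL)
    if (!is.null(refit)) {
      fits <- refit
      note <- "singular_refit"
    }
  }
  lrt <- max(0, 2 * (as.numeric(stats::logLik(fits$full)) -
                     as.numeric(stats::logLik(fits$null))))
  assoc_result(window_id, snp_rsid, cohort,
               beta = unname(lme4::fixef(fits$full)["genotype"]),
               lrt_stat = lrt,
               p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
               n_used = nrow(df), status = "tested", note = note)
}

# Vectorized OLS likelihood-ratio scan over many windows for one SNP.
# Frisch-Waugh: residualize scores and genotype on the covariate design,
# then LRT = n * log(RSS_null / RSS_full), identical to per-window lm fits.
scan_lm_core <- function(scores, genotype, design) {
  n <- ncol(scores)
  qr_x <- qr(design)
  q <- qr.Q(qr_x)
  g_res <- as.numeric(genotype - q %*% crossprod(q, genotype))
  s_res <- scores - tcrossprod(scores %*% q, q)
  gg <- sum(g_res^2)
  sg <- as.numeric(s_res %*% g_res)
  rss0 <- rowSums(s_res^2)
  beta <- sg / gg
  rss1 <- pmax(rss0 - sg^2 / gg, .Machine$double.xmin)
  lrt <- pmax(0, n * log(rss0 / rss1))
  list(beta = beta, lrt = lrt,
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

build_design <- function(meta, covariates) {
  covariates <- intersect(covariates, names(meta))
  usable <- covariates[vapply(covariates, function(cv) {
    x <- meta[[cv]]
    if (is.numeric(x)) length(unique(x)) > 1L else nlevels(factor(x)) > 1L
  }, logical(1))]
  rhs <- if (length(usable)) paste(usable, collapse = " + ") else "1"
  stats::model.matrix(stats::as.formula(paste("~", rhs)), data = meta)
}

#' Scan many windows for association with one SNP's allelic count
#'
#' The discovery engine ("lm") runs a vectorized least-squares
#' likelihood-ratio scan that reproduces [fit_discovery()] exactly; the
#' mixed engine ("lmm") calls [fit_mixed()] window by window (falling back
#' to the vectorized OLS path when the cohort has no family structure).
#'
#' @param scores numeric matrix, windows in rows (row names = window ids),
#'   samples in columns.
#' @param genotype numeric allelic counts aligned with columns.
#' @param meta per-sample covariate data.frame.
#' @param cohort cohort label; picks default covariates and engine
#'   ("1DISC" = lm, otherwise lmm).
#' @param covariates covariate names; default from [hsm_covariates()].
#' @param engine "lm" or "lmm"; default chosen from `cohort`.
#' @param snp_rsid identifier carried into results.
#' @param random passed to [fit_mixed()].
#' @return data.frame, one row per window, as in [fit_discovery()].
#' @export
scan_association <- function(scores, genotype, meta,
                             cohort = "1DISC", covariates = NULL,
                             engine = NULL, snp_rsid = NA_character_,
                             random = "family_individual") {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- as.character(seq_len(nrow(scores)))
  if (is.null(covariates))
    covariates <- hsm_covariates(
      if (cohort %in% c("1DISC", "2FOLL", "3REPL")) cohort else "array")
  if (is.null(engine)) engine <- if (cohort == "1DISC") "lm" else "lmm"

  if (engine == "lmm" && all(c("family_id", "individual_id") %in% names(meta))
      && max(table(meta$family_id)) > 1L) {
    rows <- lapply(seq_len(nrow(scores)), function(i)
      fit_mixed(scores[i, ], genotype, meta, cohort = cohort,
                covariates = covariates, random = random,
                window_id = rownames(scores)[i], snp_rsid = snp_rsid))
    return(do.call(rbind, rows))
  }

  # vectorized OLS path (discovery engine, or mixed model's OLS limit)
  note <- if (engine == "lmm") "ols_reduction" else NA_character_
  co <- if (cohort %in% c("1DISC", "2FOLL", "3REPL")) cohort else "1DISC"
  df <- data.frame(genotype = as.numeric(genotype))
  for (cv in intersect(covariates, names(meta))) df[[cv]] <- meta[[cv]]
  keep <- stats::complete.cases(df) & !is.na(colSums(scores))
  df <- droplevels(df[keep, , drop = FALSE])
  sc <- scores[, keep, drop = FALSE]
  n_used <- nrow(df)

  out <- assoc_result(window_id = rownames(scores), snp_rsid = snp_rsid,
                      cohort = cohort, n_used = n_used, status = "tested",
                      note = note)
  if (length(unique(df$genotype)) < 2L) {
    out$status <- "skipped_monomorphic"
    return(out)
  }
  const <- matrixStats_rowconst(sc)
  design <- build_design(df, covariates)
  res <- scan_lm_core(sc, df$genotype, design)
  out$beta <- res$beta; out$lrt_stat <- res$lrt; out$p_value <- res$p
  out$beta[const] <- NA_real_
  out$lrt_stat[const] <- NA_real_
  out$p_value[const] <- NA_real_
  out$status[const] <- "skipped_constant"
  out
}

matrixStats_rowconst <- function(m) {
  apply(m, 1L, function(x) max(x) == min(x))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of windows tested; must be at least 1.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  alpha / n_tests
}

#' Combine per-SNP results within multi-SNP LD blocks
#'
#' For windows in blocks holding more than one GWAS SNP, the combined
#' p-value is the arithmetic mean of the tested per-SNP p-values; the
#' direction is the sign of the beta of the minimum-p SNP. Single-SNP
#' windows pass through unchanged. Windows with no tested result are
#' dropped.
#'
#' @param results data.frame of association rows for one cohort (several
#'   SNPs may share a window_id).
#' @return data.frame with columns window_id, cohort, p_value, direction,
#'   n_snps, beta (of the minimum-p SNP).
#' @export
aggregate_multi_snp <- function(results) {
  tested <- results[results$status == "tested" & !is.na(results$p_value), ,
                    drop = FALSE]
  if (nrow(tested) == 0L)
    return(data.frame(window_id = character(), cohort = character(),
                      p_value = numeric(), direction = numeric(),
                      n_snps = integer(), beta = numeric()))
  parts <- split(tested, tested$window_id)
  rows <- lapply(parts, function(d) {
    i <- which.min(d$p_value)
    data.frame(window_id = d$window_id[1], cohort = d$cohort[1],
               p_value = mean(d$p_value),
               direction = sign(d$beta[i]),
               n_snps = nrow(d), beta = d$beta[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Statistical power of the discovery window test
#'
#' Monte-Carlo power for a single additive genotype predictor: genotypes are
#' drawn under Hardy-Weinberg equilibrium at the given minor allele
#' frequency, the phenotype carries a genotype effect sized so the
#' population variance explained is `R2 = f2 / (1 + f2)` over unit Gaussian
#' noise, and each replicate is tested by the likelihood-ratio test at
#' `alpha`. The closed-form noncentral-F power (noncentrality `n * f2`) is
#' reported alongside as a cross-check.
#'
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param n samples per replicate.
#' @param alpha test level (e.g. the Bonferroni threshold).
#' @param reps Monte-Carlo replicates, at least 100.
#' @param seed integer seed.
#' @param maf minor allele frequency for the simulated genotype.
#' @return list with `power_mc` (fraction of rejections), `power_analytic`,
#'   `se_mc` (binomial standard error), `reps`, `n`.
#' @export
power_estimate <- function(f2, n, alpha, reps = 2000L, seed = 1L,
                           maf = 0.3) {
  stopifnot(f2 > 0, n > 3, alpha > 0, alpha <= 1)
  if (reps < 100L) stop("reps must be at least 100")
  set.seed(seed)
  var_g <- 2 * maf * (1 - maf)
  b <- sqrt(f2 / var_g)              # slope giving R2 = f2/(1+f2) at sigma=1
  g <- matrix(stats::rbinom(reps * n, 2L, maf), nrow = reps)
  y <- b * g + matrix(stats::rnorm(reps * n), nrow = reps)
  gc_ <- g - rowMeans(g)
  yc <- y - rowMeans(y)
  r2 <- rowSums(gc_ * yc)^2 / (rowSums(gc_^2) * rowSums(yc^2))
  r2[rowSums(gc_^2) == 0] <- 0       # monomorphic replicate: no test signal
  lrt <- -n * log1p(-r2)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  power_mc <- mean(p < alpha)
  crit <- stats::qf(1 - alpha, df1 = 1, df2 = n - 2)
  power_analytic <- stats::pf(crit, df1 = 1, df2 = n - 2, ncp = n * f2,
                              lower.tail = FALSE)
  list(power_mc = power_mc, power_analytic = power_analytic,
       se_mc = sqrt(power_mc * (1 - power_mc) / reps),
       reps = as.integer(reps), n = as.integer(n))
}
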