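#' Filter variants on minor allele frequency and missingness
#'
#' Keeps variants whose minor allele frequency (computed on non-missing
#' calls) is at least `maf_min` and whose missing-call fraction is strictly
#' below `miss_max`. Monomorphic variants (MAF 0) are always dropped.
#'
#' @param g A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param miss_max Exclusive maximum missingness fraction (default 0.10).
#' @return The filtered [geno_matrix()].
#' @export
filter_variants <- function(g, maf_min = 0.05, miss_max = 0.10) {
  st <- variant_stats(g)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$miss < miss_max
  g[, which(keep)]
}

#' Centered kinship matrix
#'
#' `K = W %*% t(W) / p` where `W` holds the mean-centered (and mean-imputed)
#' variant columns and `p` is the number of variants — the centered
#' relatedness matrix conventional in mixed-model association. Column sums of
#' `W` are zero by construction.
#'
#' @param g A [geno_matrix()] with at least 2 variants.
#' @return A symmetric positive semidefinite samples-by-samples matrix.
#' @export
centered_kinship <- function(g) {
  p <- n_variants(g)
  if (p == 0) stop("no variants: cannot build kinship", call. = FALSE)
  w <- scale(impute_calls(g), center = TRUE, scale = FALSE)
  k <- tcrossprod(w) / p
  dimnames(k) <- list(g$samples, g$samples)
  k
}

# REML profile log-likelihood machinery on the eigenbasis of K.
# Model: y = X b + u + e, u ~ N(0, sg^2 K), e ~ N(0, se^2 I).
# With K = U diag(xi) U' and delta = se^2/sg^2, V = sg^2 U diag(xi+delta) U';
# rotate once, then each marker fit is a weighted least squares plus a 1-D
# Brent search over log(delta).

reml_neg_loglik <- function(log_delta, yr, Xr, xi) {
  delta <- exp(log_delta)
  w <- 1 / (xi + delta)
  A <- crossprod(Xr, Xr * w)
  b <- tryCatch(solve(A, crossprod(Xr, yr * w)), error = function(e) NULL)
  if (is.null(b)) return(1e10)
  r <- yr - Xr %*% b
  rss <- sum(w * r^2)
  nq <- length(yr) - ncol(Xr)
  if (rss <= 0) return(1e10)
  sg2 <- rss / nq
  0.5 * (nq * log(2 * pi * sg2) + sum(log(xi + delta)) +
           determinant(A, logarithm = TRUE)$modulus + nq)
}

reml_wls <- function(delta, yr, Xr, xi) {
  w <- 1 / (xi + delta)
  A <- crossprod(Xr, Xr * w)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(NULL)
  b <- Ainv %*% crossprod(Xr, yr * w)
  r <- yr - Xr %*% b
  nq <- length(yr) - ncol(Xr)
  sg2 <- sum(w * r^2) / nq
  list(beta = drop(b), se = sqrt(pmax(diag(Ainv), 0) * sg2),
       sigma_g2 = sg2, delta = delta)
}

fit_marker_reml <- function(yr, Xr, xi,
                            bounds = c(1e-5, 1e5), tol = 1e-8) {
  opt <- stats::optimize(reml_neg_loglik, log(bounds),
                         yr = yr, Xr = Xr, xi = xi, tol = tol)
  fit <- reml_wls(exp(opt$minimum), yr, Xr, xi)
  if (is.null(fit)) return(NULL)
  fit$neg_loglik <- opt$objective
  fit
}

check_kinship <- function(k, samples, tol_sym = 1e-10, tol_psd = 1e-8) {
  stopifnot(is.matrix(k), nrow(k) == ncol(k), nrow(k) == length(samples))
  if (max(abs(k - t(k))) > tol_sym) {
    stop("kinship matrix is not symmetric", call. = FALSE)
  }
  e <- eigen(k, symmetric = TRUE)
  if (min(e$values) < -tol_psd) {
    stop("kinship matrix is not positive semidefinite", call. = FALSE)
  }
  e$values <- pmax(e$values, 0)
  e
}

align_phenotype <- function(y, samples) {
  if (is.data.frame(y)) {
    val_col <- intersect(c("blue", "value", "B"), names(y))[1]
    id_col <- intersect(c("accession", "sample", "sample_id", "id"),
                        names(y))[1]
    if (is.na(val_col) || is.na(id_col)) {
      stop("phenotype table needs an id column (accession/sample) and a ",
           "value column (blue/value/B)", call. = FALSE)
    }
    out <- y[[val_col]][match(samples, y[[id_col]])]
  } else if (!is.null(names(y))) {
    out <- unname(y[samples])
  } else {
    stopifnot(length(y) == length(samples))
    out <- as.numeric(y)
  }
  out
}

#' Kinship-corrected linear mixed model association scan
#'
#' For each variant fits
#' `y = intercept + covariates + x beta + u + e`, with `u ~ N(0, sg^2 K)` and
#' `e ~ N(0, se^2 I)`, by exact per-marker REML: the variance ratio
#' `delta = se^2/sg^2` is optimized by Brent search on `log(delta)` in
#' `[1e-5, 1e5]` (tolerance 1e-8) on the eigenbasis of `K`, and the Wald
#' statistic `(beta/se)^2` is referred to chi-squared with 1 df. Missing
#' genotypes are mean-imputed per variant; MAF and the per-variant sample
#' count are computed before imputation. A marker collinear with the
#' covariates gets a missing p-value.
#'
#' @param g A filtered [geno_matrix()].
#' @param y Phenotype: a named numeric vector over samples, or a tibble with
#'   an id column (`accession`/`sample`) and a value column (`blue`/`value`),
#'   e.g. the output of [compute_blues()].
#' @param k Kinship matrix (defaults to [centered_kinship()] of `g`).
#' @param covariates Optional numeric matrix of per-sample fixed covariates.
#' @param alpha,fdr_q Significance levels for the Bonferroni and
#'   Benjamini-Hochberg thresholds attached to the scan.
#' @param exclude Variant ids to fit but not report (used by
#'   [conditional_scan()]).
#' @return An object of class `assoc_scan`; see [tidy.assoc_scan()] for the
#'   per-variant table and [glance.assoc_scan()] for scan-level summaries
#'   (genomic-control lambda, thresholds).
#' @export
lmm_scan <- function(g, y, k = NULL, covariates = NULL,
                     alpha = 0.05, fdr_q = 0.10, exclude = character()) {
  samples <- g$samples
  yv <- align_phenotype(y, samples)
  use <- !is.na(yv)
  if (!all(use)) {
    g <- g[which(use), ]
    if (!is.null(covariates)) covariates <- covariates[use, , drop = FALSE]
    if (!is.null(k)) k <- k[use, use, drop = FALSE]
    yv <- yv[use]
    samples <- g$samples
  }
  n <- length(yv)
  if (is.null(k)) k <- centered_kinship(g)
  e <- check_kinship(k, samples)
  U <- e$vectors
  xi <- e$values

  st <- variant_stats(g)
  X <- impute_calls(g)
  X0 <- cbind(`(intercept)` = rep(1, n), covariates)

  yr <- drop(crossprod(U, yv))
  X0r <- crossprod(U, X0)
  Gr <- crossprod(U, X)

  q0 <- ncol(X0)
  res <- purrr::map(seq_len(n_variants(g)), function(j) {
    Xr <- cbind(X0r, Gr[, j])
    fit <- fit_marker_reml(yr, Xr, xi)
    if (is.null(fit) || !is.finite(fit$se[q0 + 1]) || fit$se[q0 + 1] <= 0) {
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
    }
    b <- fit$beta[q0 + 1]
    s <- fit$se[q0 + 1]
    list(beta = b, se = s,
         p = max(stats::pchisq((b / s)^2, df = 1, lower.tail = FALSE),
                 1e-300)) # guard underflow so p stays in (0, 1]
  })
  results <- tibble::tibble(
    id = st$id, chrom = st$chrom, pos = st$pos,
    ref = g$variants$ref, alt = g$variants$alt,
    maf = st$maf, n_used = st$n_called,
    beta = purrr::map_dbl(res, "beta"),
    se = purrr::map_dbl(res, "se"),
    p_wald = purrr::map_dbl(res, "p")
  )
  if (length(exclude)) {
    results <- dplyr::filter(results, !.data$id %in% exclude)
  }
  pv <- results$p_wald[!is.na(results$p_wald)]
  thr <- if (length(pv)) {
    significance_thresholds(pv, n_tests = length(pv),
                            alpha = alpha, fdr_q = fdr_q)
  } else {
    list(bonferroni = NA_real_, fdr = NA_real_)
  }
  structure(
    list(results = results,
         lambda_gc = if (length(pv)) genomic_control_lambda(pv) else NA_real_,
         bonferroni_threshold = thr$bonferroni,
         fdr_threshold = thr$fdr,
         n_tests = length(pv), n_samples = n),
    class = "assoc_scan"
  )
}

#' Ordinary least-squares association scan (no structure correction)
#'
#' The naive per-marker regression `y = intercept + covariates + x beta + e`,
#' provided as the uncorrected baseline against which the mixed model's
#' control of population structure is demonstrated (its genomic-control
#' lambda inflates under structure where [lmm_scan()] stays near 1).
#'
#' @inheritParams lmm_scan
#' @return An `assoc_scan` object.
#' @export
ols_scan <- function(g, y, covariates = NULL, alpha = 0.05, fdr_q = 0.10) {
  lmm_scan(g, y, k = diag(length(g$samples)), covariates = covariates,
           alpha = alpha, fdr_q = fdr_q)
}

#' Conditional association scan
#'
#' Re-runs [lmm_scan()] with the (mean-imputed) genotype columns of the lead
#' markers appended as fixed covariates; the lead markers themselves are
#' excluded from the reported results. Conditioning on the causal variant of
#' a regional signal removes the signal if a single haplotype explains it.
#'
#' @inheritParams lmm_scan
#' @param lead_markers Character vector of variant ids to condition on.
#' @return An `assoc_scan` object.
#' @export
conditional_scan <- function(g, y, k = NULL, lead_markers = character(),
                             covariates = NULL, alpha = 0.05, fdr_q = 0.10) {
  if (!length(lead_markers)) {
    return(lmm_scan(g, y, k = k, covariates = covariates,
                    alpha = alpha, fdr_q = fdr_q))
  }
  missing_ids <- setdiff(lead_markers, g$variants$id)
  if (length(missing_ids)) {
    stop("lead marker(s) not in genotypes: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  lead_cols <- impute_calls(g)[, lead_markers, drop = FALSE]
  covs <- cbind(covariates, lead_cols)
  lmm_scan(g, y, k = k, covariates = covs, alpha = alpha, fdr_q = fdr_q,
           exclude = lead_markers)
}

#' Bonferroni and Benjamini-Hochberg significance cuts
#'
#' @param pvals P-values in (0, 1].
#' @param n_tests Number of tests (defaults to `length(pvals)`).
#' @param alpha Family-wise error rate for the Bonferroni cut.
#' @param fdr_q Target false discovery rate for the step-up cut.
#' @return A list with `bonferroni` (`alpha / n_tests`) and `fdr` (the
#'   largest `p_(i) <= i * q / m`, or `NA` if none qualifies).
#' @export
significance_thresholds <- function(pvals, n_tests = length(pvals),
                                    alpha = 0.05, fdr_q = 0.10) {
  if (!length(pvals)) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(pvals > 0 & pvals <= 1))
  ps <- sort(pvals)
  m <- length(ps)
  ok <- which(ps <= seq_len(m) * fdr_q / m)
  list(
    bonferroni = alpha / n_tests,
    fdr = if (length(ok)) ps[max(ok)] else NA_real_
  )
}

#' Median of the chi-squared distribution with one degree of freedom
#'
#' The denominator of the genomic-control statistic, computed by inverse CDF
#' (approximately 0.4549).
#'
#' @return A scalar.
#' @export
chisq1_median <- function() stats::qchisq(0.5, df = 1)

#' Genomic-control lambda
#'
#' Converts p-values to chi-squared(1) quantiles and divides their observed
#' median by the null chi-squared(1) median. Lambda near 1 indicates
#' calibrated tests; inflation signals uncorrected structure.
#'
#' @param pvals P-values in (0, 1].
#' @return A positive scalar.
#' @export
genomic_control_lambda <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  chi <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chi) / chisq1_median()
}

#' Homozygote effect size
#'
#' Per-allele effects from the inbred 0/1 coding are doubled to express the
#' expected phenotype difference between the two homozygote classes.
#'
#' @param beta Per-allele effect(s), ug/g DW.
#' @return `2 * beta`, same units.
#' @export
effect_size_homozygous <- function(beta) 2 * beta

#' Mann-Whitney-Wilcoxon two-group test
#'
#' Exact two-sided p-value when both groups have at most 20 observations and
#' no ties are present; otherwise the normal approximation with mid-ranks,
#' tie-corrected variance and continuity correction.
#'
#' @param values Numeric measurements.
#' @param group_labels Two-level grouping aligned with `values`.
#' @return A one-row tibble with `u` (the U statistic for the first group),
#'   `p_value` and `method`.
#' @export
group_difference_test <- function(values, group_labels) {
  f <- factor(group_labels)
  if (nlevels(f) != 2) stop("exactly two groups required", call. = FALSE)
  x <- values[f == levels(f)[1]]
  z <- values[f == levels(f)[2]]
  if (!length(x) || !length(z)) stop("both groups must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, z)) > 0
  exact <- length(x) <= 20 && length(z) <= 20 && !ties
  wt <- stats::wilcox.test(x, z, exact = exact, correct = !exact)
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation, tie-corrected"
  )
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("<assoc_scan> %d variants, %d samples; lambda_gc = %.3f\n",
              x$n_tests, x$n_samples, x$lambda_gc))
  cat(sprintf("  Bonferroni cut %.3g; FDR cut %s\n", x$bonferroni_threshold,
              if (is.na(x$fdr_threshold)) "none"
              else format(x$fdr_threshold, digits = 3)))
  top <- dplyr::arrange(x$results, .data$p_wald)
  print(utils::head(top, 5))
  invisible(x)
}

#' Per-variant association results
#'
#' @param x An `assoc_scan`.
#' @param ... Ignored.
#' @return A tibble with one row per tested variant: `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`, `n_used`, `beta`, `se`, `p_wald`.
#' @export
tidy.assoc_scan <- function(x, ...) x$results

#' Scan-level association summary
#'
#' @param x An `assoc_scan`.
#' @param ... Ignored.
#' @return A one-row tibble: `n_tests`, `n_samples`, `lambda_gc`,
#'   `bonferroni_threshold`, `fdr_threshold`.
#' @export
glance.assoc_scan <- function(x, ...) {
  tibble::tibble(
    n_tests = x$n_tests, n_samples = x$n_samples,
    lambda_gc = x$lambda_gc,
    bonferroni_threshold = x$bonferroni_threshold,
    fdr_threshold = x$fdr_threshold
  )
}
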