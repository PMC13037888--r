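#' Genotype matrix for inbred (haploid-coded) lines
#'
#' A light container for a samples-by-variants call matrix over inbred lines.
#' Each accession contributes one haplotype, so calls are coded `0` (reference
#' allele), `1` (alternate allele) or `NA` (missing). Per-call read depth (DP)
#' and genotype quality (GQ) travel alongside the calls so that quality
#' filtering can be applied downstream.
#'
#' @param calls Integer matrix, samples in rows, variants in columns; entries
#'   in `{0, 1, NA}`.
#' @param variants Data frame with one row per variant and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`; an `id` column is added if absent.
#' @param samples Character vector of sample identifiers (row order of
#'   `calls`).
#' @param dp,gq Optional matrices of the same shape as `calls` holding
#'   per-call read depth and Phred genotype quality.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `variants` (tibble), `samples`, `dp`, `gq`.
#' @export
geno_matrix <- function(calls, variants, samples, dp = NULL, gq = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- tibble::as_tibble(variants)
  stopifnot(
    nrow(calls) == length(samples),
    ncol(calls) == nrow(variants),
    all(c("chrom", "pos", "ref", "alt") %in% names(variants))
  )
  bad <- stats::na.omit(unique(as.vector(calls)))
  if (!all(bad %in% c(0L, 1L))) {
    stop("calls must be coded 0/1/NA (inbred haploid coding)", call. = FALSE)
  }
  if (!"id" %in% names(variants)) {
    variants$id <- paste0(variants$chrom, ":", variants$pos)
  }
  # positions must increase within each chromosome
  ok <- all(unlist(lapply(split(variants$pos, variants$chrom),
                          function(p) all(diff(p) > 0))))
  if (!ok) stop("variant positions must be strictly increasing within chrom",
                call. = FALSE)
  for (m in list(dp, gq)) {
    if (!is.null(m)) stopifnot(all(dim(m) == dim(calls)))
  }
  dimnames(calls) <- list(samples, variants$id)
  structure(
    list(calls = calls, variants = variants, samples = samples,
         dp = dp, gq = gq),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants (%.1f%% missing)\n",
              n_samples(x), n_variants(x),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname geno_matrix
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param i Sample index (logical, integer or character).
#' @param j Variant index (logical, integer or character id).
#' @param ... Ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_variants(x))
  if (is.character(j)) j <- match(j, x$variants$id)
  if (is.character(i)) i <- match(i, x$samples)
  geno_matrix(
    calls = x$calls[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    samples = x$samples[i],
    dp = if (!is.null(x$dp)) x$dp[i, j, drop = FALSE],
    gq = if (!is.null(x$gq)) x$gq[i, j, drop = FALSE]
  )
}

#' Per-variant minor allele frequency and missingness
#'
#' MAF is computed on non-missing calls; for 0/1 inbred coding the alternate
#' allele frequency is folded at 0.5.
#'
#' @param g A `geno_matrix`.
#' @return A tibble with columns `id`, `chrom`, `pos`, `af` (alternate allele
#'   frequency), `maf`, `miss` (fraction of missing calls), `n_called`.
#' @export
variant_stats <- function(g) {
  af <- unname(colMeans(g$calls, na.rm = TRUE))
  af[is.nan(af)] <- NA_real_
  tibble::tibble(
    id = g$variants$id,
    chrom = g$variants$chrom,
    pos = g$variants$pos,
    af = af,
    maf = pmin(af, 1 - af),
    miss = unname(colMeans(is.na(g$calls))),
    n_called = unname(colSums(!is.na(g$calls)))
  )
}

#' Mean-impute missing calls per variant
#'
#' Missing calls are replaced by the variant's alternate-allele frequency
#' (its column mean), the convention used when building the kinship matrix and
#' when testing markers in the mixed-model scan.
#'
#' @param g A `geno_matrix`.
#' @return A numeric matrix (samples x variants) with no missing values.
#' @export
impute_calls <- function(g) {
  x <- g$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  x
}

#' Tidy a genotype matrix into long format
#'
#' @param x A `geno_matrix`.
#' @param ... Ignored.
#' @return A tibble with one row per (sample, variant) call.
#' @export
tidy.geno_matrix <- function(x, ...) {
  long <- tibble::tibble(
    sample = rep(x$samples, times = n_variants(x)),
    id = rep(x$variants$id, each = n_samples(x)),
    call = as.vector(x$calls)
  )
  if (!is.null(x$dp)) long$dp <- as.vector(x$dp)
  if (!is.null(x$gq)) long$gq <- as.vector(x$gq)
  dplyr::left_join(long, x$variants, by = "id")
}
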