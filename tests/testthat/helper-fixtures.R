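# Small in-code fixtures shared across test files.

# Genotype matrix from a plain 0/1/NA matrix; positions default to 1..p.
tiny_geno <- function(calls, pos = NULL, samples = NULL, dp = NULL, gq = NULL,
                      chrom = "chr1") {
  calls <- as.matrix(calls)
  p <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(p)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(calls)))
  variants <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             ref = "A", alt = "T")
  geno_matrix(calls, variants, samples, dp = dp, gq = gq)
}

# Independent brute-force GLS oracle: grid-search the variance ratio over
# grid_n log-spaced points maximizing the REML criterion directly, then
# refine with a fine grid around the coarse argmin (still plain evaluation,
# no shared code with the fitted path). Returns the last-column (marker)
# effect, its standard error and Wald p.
gls_grid_oracle <- function(y, X, K, grid_n = 1e4,
                            bounds = c(1e-5, 1e5)) {
  n <- length(y)
  e <- eigen(K, symmetric = TRUE)
  U <- e$vectors
  xi <- pmax(e$values, 0)
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  q <- ncol(X)

  eval_delta <- function(d) {
    w <- 1 / (xi + d)
    A <- crossprod(Xr, Xr * w)
    b <- tryCatch(solve(A, crossprod(Xr, yr * w)), error = function(e) NULL)
    if (is.null(b)) return(NULL)
    r <- yr - Xr %*% b
    rss <- sum(w * r^2)
    if (rss <= 0) return(NULL)
    sg2 <- rss / (n - q)
    nll <- 0.5 * ((n - q) * log(2 * pi * sg2) + sum(log(xi + d)) +
                    determinant(A, logarithm = TRUE)$modulus + (n - q))
    se <- sqrt(unname(diag(solve(A))[q]) * sg2)
    list(nll = nll, beta = unname(b[q]), se = se,
         p = stats::pchisq((b[q] / se)^2, 1, lower.tail = FALSE))
  }
  search <- function(grid) {
    best <- NULL
    best_d <- NA
    for (d in grid) {
      fit <- eval_delta(d)
      if (!is.null(fit) && (is.null(best) || fit$nll < best$nll)) {
        best <- fit
        best_d <- d
      }
    }
    list(fit = best, d = best_d)
  }
  lg <- seq(log(bounds[1]), log(bounds[2]), length.out = grid_n)
  coarse <- search(exp(lg))
  step <- lg[2] - lg[1]
  fine <- search(exp(seq(log(coarse$d) - 2 * step, log(coarse$d) + 2 * step,
                         length.out = 2000)))
  fine$fit[c("beta", "se", "p")]
}

# One seeded structured population with a single causal SNP and phenotype.
sim_causal_dataset <- function(seed, n_samples = 100, n_variants = 300,
                               effect = 8, true_h2 = 0.75,
                               target_maf = 0.3, ...) {
  cfg <- sim_config(n_samples = n_samples, n_variants = n_variants, ...)
  pop <- simulate_island_population(cfg, seed)
  st <- variant_stats(pop$geno)
  ok <- !is.na(st$maf) & st$maf > 0 & st$miss == 0
  id <- st$id[ok][which.min(abs(st$maf[ok] - target_maf))]
  truth <- set_causal_effects(pop$truth, pop$geno, id, effect,
                              true_h2 = true_h2)
  pheno <- suppressWarnings(simulate_trait(pop$geno, truth, cfg, seed))
  list(cfg = cfg, geno = pop$geno, truth = truth, pheno = pheno,
       causal_id = id)
}

expect_junction_equal <- function(call, truth) {
  expect_equal(call$type, truth$type)
  expect_equal(call$length, truth$length)
  expect_equal(call$sequence, truth$sequence)
}
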