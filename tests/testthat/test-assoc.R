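test_that("variant filter applies MAF and missingness rules", {
  calls <- matrix(0L, nrow = 100, ncol = 3)
  calls[1:3, 1] <- 1L                 # MAF 0.03 -> dropped
  calls[1:30, 2] <- 1L                # MAF 0.30, no missing -> kept
  calls[1:30, 3] <- 1L
  calls[31:45, 3] <- NA_integer_      # 15% missing -> dropped
  g <- tiny_geno(calls)
  f <- filter_variants(g, maf_min = 0.05, miss_max = 0.10)
  expect_equal(f$variants$pos, 2L)

  mono <- tiny_geno(matrix(0L, 10, 1))
  expect_equal(n_variants(filter_variants(mono)), 0)
})

test_that("centered kinship matches the hand-computed outer product", {
  g <- tiny_geno(matrix(c(0L, 1L), ncol = 1))
  k <- centered_kinship(g)
  expect_equal(unname(k), rbind(c(0.25, -0.25), c(-0.25, 0.25)))

  # duplicate samples give identical rows; centering identity holds
  cfg <- sim_config(n_samples = 20, n_variants = 50, missing_rate = 0.05)
  gg <- simulate_island_population(cfg, 13)$geno
  w <- scale(impute_calls(gg), center = TRUE, scale = FALSE)
  expect_lt(max(abs(colSums(w))), 1e-10)
  dup <- gg[c(1, 1, 2:10), ]
  kd <- centered_kinship(dup)
  expect_equal(kd[1, ], kd[2, ])
  expect_error(centered_kinship(gg[, integer(0)]), "no variants")
})

test_that("identity kinship reduces the mixed model to OLS", {
  set.seed(6)
  n <- 40
  x <- rbinom(n, 1, 0.4)
  y <- 2 + 1.5 * x + rnorm(n)
  g <- tiny_geno(matrix(as.integer(x), ncol = 1))
  scan <- lmm_scan(g, setNames(y, g$samples), k = diag(n))
  fit <- summary(lm(y ~ x))$coefficients
  ols_p <- pchisq((fit[2, 1] / fit[2, 2])^2, 1, lower.tail = FALSE)
  expect_equal(tidy(scan)$beta, fit[2, 1], tolerance = 1e-6)
  expect_equal(tidy(scan)$se, fit[2, 2], tolerance = 1e-6)
  expect_equal(tidy(scan)$p_wald, ols_p, tolerance = 1e-6)
})

test_that("an exact linear phenotype recovers its coefficient", {
  set.seed(7)
  x <- rep(c(0L, 1L), each = 10)
  g <- tiny_geno(cbind(x, rbinom(20, 1, 0.5)))
  y <- 3 + 4.5 * x
  scan <- lmm_scan(g, setNames(y, g$samples), k = diag(20))
  expect_equal(tidy(scan)$beta[1], 4.5, tolerance = 1e-6)
  expect_equal(tidy(scan)$p_wald[1], 1e-300) # clamped underflow
})

test_that("mixed model matches the brute-force GLS oracle on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:10, 1)
    W <- matrix(rnorm(n * 3), n)
    K <- tcrossprod(W) / 3
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1] <- 1 - x[1]
    y <- 1 + rnorm(1) * x + drop(chol(K + diag(n) * 0.3) %*% rnorm(n))
    g <- tiny_geno(matrix(as.integer(x), ncol = 1))
    scan <- tidy(lmm_scan(g, setNames(y, g$samples), k = K))
    oracle <- gls_grid_oracle(y, cbind(1, x), K)
    expect_equal(scan$beta, oracle$beta, tolerance = 1e-4)
    expect_equal(scan$se, oracle$se, tolerance = 1e-4)
    expect_equal(scan$p_wald, oracle$p, tolerance = 1e-3)
  }
})

test_that("marker collinear with a covariate reports missing p", {
  set.seed(8)
  x <- rep(c(0L, 1L), each = 8)
  g <- tiny_geno(matrix(x, ncol = 1))
  y <- rnorm(16)
  scan <- lmm_scan(g, setNames(y, g$samples), k = diag(16),
                   covariates = cbind(lead = x))
  expect_true(is.na(tidy(scan)$p_wald))
})

test_that("non-PSD kinship is rejected", {
  g <- tiny_geno(matrix(c(0L, 1L, 0L, 1L), ncol = 1))
  k <- diag(4); k[1, 1] <- -1
  expect_error(lmm_scan(g, setNames(rnorm(4), g$samples), k = k),
               "positive semidefinite")
})

test_that("conditional scan equals the plain scan for an empty lead list", {
  d <- sim_causal_dataset(31, n_samples = 60, n_variants = 80,
                          missing_rate = 0)
  y <- setNames(rnorm(60), d$geno$samples)
  g <- filter_variants(d$geno, 0.05, 0.10)
  k <- centered_kinship(g)
  s0 <- lmm_scan(g, y, k = k)
  s1 <- conditional_scan(g, y, k = k, lead_markers = character())
  expect_equal(tidy(s0), tidy(s1))
  expect_error(conditional_scan(g, y, k = k, lead_markers = "chr1:0"),
               "chr1:0")
})

test_that("conditioning on the causal variant removes its regional signal", {
  hits_killed <- 0
  n_scans <- 20
  for (seed in seq_len(n_scans)) {
    d <- sim_causal_dataset(seed + 100, n_samples = 100, n_variants = 150,
                            effect = 8, missing_rate = 0,
                            contamination_rate = 0)
    blues <- compute_blues(min_replicate_filter(zscore_outlier_filter(d$pheno)))
    g <- filter_variants(d$geno, 0.05, 0.10)
    if (!d$causal_id %in% g$variants$id) next
    k <- centered_kinship(g)
    cond <- conditional_scan(g, blues, k = k, lead_markers = d$causal_id)
    res <- tidy(cond)
    pos0 <- g$variants$pos[g$variants$id == d$causal_id]
    near <- res[abs(res$pos - pos0) <= 25000, ]
    if (all(near$p_wald > cond$bonferroni_threshold, na.rm = TRUE)) {
      hits_killed <- hits_killed + 1
    }
  }
  expect_gte(hits_killed, round(0.9 * n_scans))
})

test_that("conditioning on an uncorrelated marker barely moves the top hit", {
  d <- sim_causal_dataset(55, n_samples = 150, n_variants = 120, effect = 8,
                          missing_rate = 0, contamination_rate = 0)
  blues <- compute_blues(min_replicate_filter(zscore_outlier_filter(d$pheno)))
  g <- filter_variants(d$geno, 0.05, 0.10)
  k <- centered_kinship(g)
  s0 <- tidy(lmm_scan(g, blues, k = k))
  top <- s0$id[which.min(s0$p_wald)]
  x_top <- impute_calls(g)[, top]
  r2 <- apply(impute_calls(g), 2, function(v) cor(v, x_top)^2)
  r2[top] <- NA
  lead <- names(which.min(r2))  # essentially uncorrelated marker
  s1 <- tidy(conditional_scan(g, blues, k = k, lead_markers = lead))
  lp0 <- -log10(s0$p_wald[s0$id == top])
  lp1 <- -log10(s1$p_wald[s1$id == top])
  expect_lt(abs(lp1 - lp0) / lp0, 0.10)
})

test_that("significance thresholds follow Bonferroni and BH step-up", {
  thr <- significance_thresholds(runif(20, 0.3, 1), n_tests = 20,
                                 alpha = 0.05)
  expect_equal(thr$bonferroni, 0.0025)
  thr2 <- significance_thresholds(c(0.001, 0.02, 0.03, 0.5), fdr_q = 0.10)
  expect_equal(thr2$fdr, 0.03)
  thr3 <- significance_thresholds(rep(1, 5))
  expect_true(is.na(thr3$fdr))
  expect_error(significance_thresholds(numeric(0)), "empty")
})

test_that("genomic-control lambda is calibrated and scales with inflation", {
  expect_equal(genomic_control_lambda(rep(0.5, 11)), 1, tolerance = 1e-10)
  set.seed(9)
  p <- runif(1e5)
  expect_lt(abs(genomic_control_lambda(p) - 1), 0.02)
  chi2 <- 2 * qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(chi2, 1, lower.tail = FALSE)
  expect_equal(genomic_control_lambda(p2), 2, tolerance = 0.02)
})

test_that("homozygote effects are twice the per-allele beta", {
  expect_equal(effect_size_homozygous(0), 0)
  expect_equal(effect_size_homozygous(6.62 / 2), 6.62)
  expect_equal(effect_size_homozygous(-1.5), -3.0)
})

test_that("MWW test is exact for small untied groups and handles ties", {
  out <- group_difference_test(c(1, 2, 3, 4, 5, 6),
                               rep(c("a", "b"), each = 3))
  expect_equal(out$p_value, 0.1)   # 2 / choose(6, 3)
  expect_equal(out$u, 0)
  expect_equal(out$method, "exact")

  same <- group_difference_test(rep(1:5, 2), rep(c("a", "b"), each = 5))
  expect_gte(same$p_value, 0.99)

  set.seed(10)
  big <- group_difference_test(c(rnorm(100), rnorm(100, 2)),
                               rep(c("a", "b"), each = 100))
  expect_lt(big$p_value, 1e-10)
  expect_error(group_difference_test(1:3, rep("a", 3)), "two groups")
})

test_that("beta recovery: median estimate within 10% at n = 200", {
  betas <- sapply(1:15, function(seed) {
    set.seed(seed + 500)
    n <- 200
    x <- rbinom(n, 1, 0.3)
    # marker contributes ~20% of phenotypic variance
    y <- 3 * x + rnorm(n, 0, sqrt(4 * 9 * 0.3 * 0.7))
    g <- tiny_geno(matrix(as.integer(x), ncol = 1))
    tidy(lmm_scan(g, setNames(y, g$samples), k = diag(n)))$beta
  })
  expect_lt(abs(median(betas) - 3) / 3, 0.10)
})

test_that("permuting the phenotype breaks association", {
  # n large enough that the chi-squared Wald reference is in its regime
  d <- sim_causal_dataset(77, n_samples = 200, n_variants = 120, effect = 8,
                          missing_rate = 0, contamination_rate = 0)
  blues <- compute_blues(min_replicate_filter(zscore_outlier_filter(d$pheno)))
  g <- filter_variants(d$geno, 0.05, 0.10)
  k <- centered_kinship(g)
  set.seed(11)
  hits <- sapply(1:20, function(i) {
    yp <- blues
    yp$blue <- sample(yp$blue)
    s <- lmm_scan(g, yp, k = k)
    min(tidy(s)$p_wald, na.rm = TRUE) < s$bonferroni_threshold
  })
  expect_lte(sum(hits), 3) # 20 x 0.05 plus binomial slack
})
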