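test_that("config validation rejects impossible populations", {
  expect_error(sim_config(n_subpops = 10, n_samples = 5), "invalid config")
  expect_error(sim_config(maf_floor = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(bottleneck_diversity = -1), ">= 0")
})

test_that("zero diversity yields a monomorphic population, deterministically", {
  cfg <- sim_config(n_samples = 20, n_variants = 50, n_subpops = 1,
                    bottleneck_diversity = 0, missing_rate = 0)
  g <- simulate_island_population(cfg, 3)$geno
  st <- variant_stats(g)
  expect_true(all(st$maf == 0))

  cfg2 <- sim_config(n_samples = 30, n_variants = 80)
  a <- simulate_island_population(cfg2, 17)
  b <- simulate_island_population(cfg2, 17)
  expect_identical(a$geno$calls, b$geno$calls)
  expect_identical(a$geno$dp, b$geno$dp)
  expect_identical(a$truth$subpop_labels, b$truth$subpop_labels)
})

test_that("realized MAF spectrum respects the configured floor", {
  cfg <- sim_config(n_samples = 50, n_variants = 300, maf_floor = 0.1,
                    missing_rate = 0)
  st <- variant_stats(simulate_island_population(cfg, 5)$geno)
  poly <- st$maf[st$maf > 0]
  expect_true(all(poly >= 0.1))
})

test_that("subpopulation allele-frequency differentiation is present", {
  cfg <- sim_config(n_samples = 90, n_variants = 200, n_subpops = 3,
                    fst = 0.3, missing_rate = 0)
  pop <- simulate_island_population(cfg, 21)
  g <- filter_variants(pop$geno, 0.1, 1)
  sub <- pop$truth$subpop_labels
  # mean squared frequency difference across subpops well above binomial noise
  freq_by_pop <- vapply(unique(sub), function(s) {
    colMeans(g$calls[sub == s, , drop = FALSE], na.rm = TRUE)
  }, numeric(n_variants(g)))
  spread <- mean(apply(freq_by_pop, 1, var))
  expect_gt(spread, 0.02)
})

test_that("trait generator reproduces causal effects and the intercept", {
  # zero effects, zero residual/block variance -> all B equal the intercept
  cfg <- sim_config(n_samples = 10, n_variants = 20, residual_sd = 0,
                    block_sd = 0, contamination_rate = 0, trait_mean = 20)
  pop <- simulate_island_population(cfg, 2)
  ph <- simulate_trait(pop$geno, pop$truth, cfg, 2)
  expect_true(all(ph$B == 20))

  # single causal SNP: genotype-class mean difference recovers the effect
  d <- sim_causal_dataset(8, n_samples = 200, n_variants = 150, effect = 6,
                          true_h2 = 0.75, missing_rate = 0,
                          contamination_rate = 0)
  x <- d$geno$calls[, d$causal_id]
  acc_mean <- tapply(d$pheno$B, d$pheno$accession, mean)
  diff <- mean(acc_mean[x[names(acc_mean)] == 1]) -
    mean(acc_mean[x[names(acc_mean)] == 0])
  expect_lt(abs(diff - 6), 1)

  # missing causal id errors by name
  expect_error(
    set_causal_effects(pop$truth, pop$geno, "chr9:999", 1),
    "chr9:999"
  )
})

test_that("trait table is one row per accession x block x replicate", {
  cfg <- sim_config(n_samples = 12, n_variants = 20, n_blocks = 4, n_reps = 4)
  pop <- simulate_island_population(cfg, 4)
  ph <- simulate_trait(pop$geno, pop$truth, cfg, 4)
  expect_equal(nrow(ph), 12 * 4)
  expect_false(anyDuplicated(ph$sample_id) > 0)
  expect_equal(sort(unique(ph$block)), paste0("block", 1:4))
})

test_that("clean traits rarely trip the contamination filter", {
  cfg <- sim_config(n_samples = 100, n_variants = 20, contamination_rate = 0)
  pop <- simulate_island_population(cfg, 6)
  ph <- simulate_trait(pop$geno, pop$truth, cfg, 6)
  kept <- zscore_outlier_filter(ph, c("Cr", "Ti"))
  # fraction removed bounded by the nominal two-channel tail: the skewed
  # lognormal sentinel channels put about 1% per channel beyond |z| = 3
  expect_lte(1 - nrow(kept) / nrow(ph), 0.05)
})

test_that("depth simulator hits the expected means and is seeded", {
  p1 <- simulate_depth_profile(4000, c(1000, 3000, 1), depth_mean = 30,
                               dispersion = 0, seed = 1)
  expect_lt(abs(mean(p1$depth) - 30), 1)

  p2 <- simulate_depth_profile(4000, c(1000, 3000, 2), depth_mean = 30,
                               dispersion = 0, seed = 1)
  expect_lt(abs(mean(p2$depth[1001:3000]) - 60), 2)
  expect_lt(abs(mean(p2$depth[c(1:1000, 3001:4000)]) - 30), 2)

  p3 <- simulate_depth_profile(4000, c(1000, 3000, 2), depth_mean = 30,
                               dispersion = 0, seed = 1)
  expect_identical(p2$depth, p3$depth)
  expect_error(simulate_depth_profile(100, c(10, 50, 1), depth_mean = -1),
               "invalid config")
})

test_that("junction constructor records its truth for all three types", {
  ref <- random_reference(3000, seed = 5)
  jb <- make_junction_sequence(ref, 400, 2600, "blunt")
  expect_junction_equal(jb$truth, junction_call("blunt", 0, ""))

  jm <- make_junction_sequence(ref, 400, 2600, "microhomology",
                               motif = "TACATA")
  expect_equal(jm$truth$length, 6)
  # the motif both ends copy 1 and starts copy 2 in the edited reference
  expect_equal(substr(jm$reference, 2595, 2600), "TACATA")
  expect_equal(substr(jm$reference, 400, 405), "TACATA")

  ji <- make_junction_sequence(ref, 400, 2600, "insertion",
                               insert = "TATGATCATAAAGTGTTACTACTCAT")
  expect_equal(ji$truth$length, 26)
  expect_error(
    make_junction_sequence(ref, 400, 420, "microhomology",
                           motif = strrep("A", 21)),
    "too long"
  )
})

test_that("truth YAML round-trips causal effects and junction truth", {
  cfg <- sim_config(n_samples = 15, n_variants = 30)
  pop <- simulate_island_population(cfg, 9)
  st <- variant_stats(pop$geno)
  id <- st$id[which.max(st$maf)]
  truth <- set_causal_effects(pop$truth, pop$geno, id, 5.5, true_h2 = 0.6)
  truth$junction_truth <- junction_call("microhomology", 3, "TTA")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(truth, path)
  rt <- read_truth_yaml(path)
  expect_equal(rt$causal_snps, truth$causal_snps)
  expect_equal(rt$true_h2, 0.6)
  expect_equal(rt$junction_truth$sequence, "TTA")
  expect_equal(rt$subpop_labels, truth$subpop_labels)
})
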