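make_ionome <- function(B, Cr = rep(0.5, length(B)), Ti = rep(2, length(B)),
                        accession = paste0("a", seq_along(B)),
                        block = "block1") {
  tibble::tibble(
    sample_id = paste0("r", seq_along(B)), accession = accession,
    block = block, replicate = seq_along(B), B = B, Cr = Cr, Ti = Ti
  )
}

test_that("z-score filter removes the contaminated plant and only it", {
  # 12 rows, Ti all zero except one at 12: its z is 3.175 > 3
  tab <- make_ionome(B = rep(10, 12), Ti = c(rep(0, 11), 12))
  out <- zscore_outlier_filter(tab)
  expect_equal(nrow(out), 11)
  expect_false("r12" %in% out$sample_id)
  # the z-score itself, computed as the filter does
  z <- (12 - mean(tab$Ti)) / sd(tab$Ti)
  expect_equal(round(z, 3), 3.175)
})

test_that("z-score filter is identity for constant channels and infinite cuts", {
  tab <- make_ionome(B = rep(7, 6))
  expect_equal(zscore_outlier_filter(tab), tab)   # all z = 0
  tab2 <- make_ionome(B = c(1, 2, 3, 50))
  expect_equal(zscore_outlier_filter(tab2, threshold = Inf), tab2)
})

test_that("z-scores are single-pass: no re-filtering after removal", {
  # an extreme point masks a moderate one; one pass keeps the moderate point
  B <- c(rep(10, 10), 14, 100)
  tab <- make_ionome(B = B)
  out <- zscore_outlier_filter(tab, channels = "B")
  z1 <- abs((B - mean(B)) / sd(B))
  expect_equal(out$sample_id, tab$sample_id[z1 <= 3])
  # iterative filtering would also remove the 14; single-pass keeps it
  expect_true("r11" %in% out$sample_id)
})

test_that("replicate floor drops whole accessions and is idempotent", {
  tab <- dplyr::bind_rows(
    make_ionome(rep(10, 4), accession = rep("keep", 4)),
    make_ionome(rep(10, 2), accession = rep("drop", 2))
  )
  out <- min_replicate_filter(tab, min_reps = 3)
  expect_setequal(unique(out$accession), "keep")
  expect_equal(min_replicate_filter(out, 3), out)
  expect_equal(min_replicate_filter(tab, 1), tab)
})

test_that("BLUEs equal accession means for balanced complete designs", {
  set.seed(1)
  acc <- paste0("a", 1:20)
  tab <- tidyr::expand_grid(accession = acc, block = paste0("block", 1:4))
  tab$sample_id <- paste(tab$accession, tab$block)
  tab$replicate <- 1L
  tab$B <- rnorm(nrow(tab), 20, 3)
  tab$Cr <- 0.5; tab$Ti <- 2
  blues <- compute_blues(tab)
  means <- tapply(tab$B, tab$accession, mean)
  expect_equal(blues$blue[match(names(means), blues$accession)],
               as.vector(means), tolerance = 1e-8)
  expect_true(all(blues$n_reps_used == 4))
})

test_that("single-block BLUEs fall back to replicate means with a warning", {
  tab <- make_ionome(B = c(10, 12, 20, 22),
                     accession = c("a", "a", "b", "b"))
  expect_warning(blues <- compute_blues(tab), "single block")
  expect_equal(sort(blues$blue), c(11, 21))
})

test_that("BLUEs are shift-equivariant", {
  set.seed(2)
  tab <- dplyr::bind_rows(lapply(1:3, function(b) {
    make_ionome(rnorm(10, 20), accession = paste0("a", 1:10),
                block = paste0("block", b))
  }))
  b0 <- compute_blues(tab)
  tab$B <- tab$B + 7
  b1 <- compute_blues(tab)
  expect_equal(b1$blue, b0$blue + 7, tolerance = 1e-8)
})

test_that("BLUEs beat raw accession means under unbalanced block effects", {
  set.seed(3)
  n_acc <- 100
  gtruth <- rnorm(n_acc, 0, 3)
  blocks <- paste0("block", 1:4)
  beff <- rnorm(4, 0, 5)
  tab <- tidyr::expand_grid(i = seq_len(n_acc), b = 1:4)
  tab <- tab[runif(nrow(tab)) > 0.35, ]          # incomplete design
  tab <- tibble::tibble(
    sample_id = paste(tab$i, tab$b), accession = paste0("a", tab$i),
    block = blocks[tab$b], replicate = tab$b,
    B = 20 + gtruth[tab$i] + beff[tab$b] + rnorm(nrow(tab), 0, 1),
    Cr = 0.5, Ti = 2
  )
  tab <- min_replicate_filter(tab, 2)
  blues <- compute_blues(tab)
  means <- tapply(tab$B, tab$accession, mean)
  idx <- match(blues$accession, paste0("a", seq_len(n_acc)))
  truthv <- gtruth[idx]
  rmse <- function(est) {
    e <- est - mean(est)
    t <- truthv - mean(truthv)
    sqrt(mean((e - t)^2))
  }
  expect_lt(rmse(blues$blue),
            rmse(unname(means[match(blues$accession, names(means))])))
})

test_that("heritability hits its algebraic extremes", {
  # replicates identical within accession, accessions differ -> H2 = 1
  tab <- make_ionome(B = rep(c(10, 20, 30), each = 3),
                     accession = rep(c("a", "b", "c"), each = 3))
  # boundary fit (residual variance 0) provokes lme4 convergence chatter
  expect_equal(suppressWarnings(broad_sense_heritability(tab))$h2, 1)

  # pure noise, no accession signal -> H2 near 0
  set.seed(4)
  tab2 <- make_ionome(B = rnorm(300),
                      accession = rep(paste0("a", 1:75), each = 4))
  expect_lt(broad_sense_heritability(tab2)$h2, 0.1)

  # fully constant table -> 0/0/0
  tab3 <- make_ionome(B = rep(5, 8), accession = rep(c("a", "b"), each = 4))
  h <- broad_sense_heritability(tab3)
  expect_equal(c(h$h2, h$var_line, h$var_residual), c(0, 0, 0))
})

test_that("heritability is invariant to affine rescaling", {
  set.seed(5)
  tab <- make_ionome(B = rnorm(60, 20, 4),
                     accession = rep(paste0("a", 1:15), each = 4))
  h0 <- broad_sense_heritability(tab)$h2
  tab$B <- 3.7 * tab$B + 11
  expect_equal(broad_sense_heritability(tab)$h2, h0, tolerance = 1e-6)
})

test_that("glance/tidy expose the variance components", {
  tab <- make_ionome(B = rep(c(10, 20), each = 4),
                     accession = rep(c("a", "b"), each = 4))
  h <- suppressWarnings(broad_sense_heritability(tab))
  g <- glance(h)
  expect_named(g, c("h2", "var_line", "var_residual"))
  expect_equal(g$h2, h$var_line / (h$var_line + h$var_residual))
})
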