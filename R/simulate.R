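#' Simulation configuration for a structured inbred island population
#'
#' Bundles the knobs of the synthetic-data generator. Defaults describe the
#' regime the package targets: a small, recently bottlenecked population of
#' selfing lines split into differentiated island subpopulations, phenotyped
#' in a replicated randomized block design, and sequenced at moderate depth.
#'
#' @param n_samples Number of inbred accessions (one haplotype each).
#' @param n_variants Total variant sites emitted (polymorphic + monomorphic).
#' @param n_subpops Number of island subpopulations.
#' @param bottleneck_diversity Per-site Watterson's theta target; the expected
#'   number of segregating sites is `theta * a_n * region_length`. `0` gives a
#'   fully monomorphic population.
#' @param region_length Length in bp of the simulated region.
#' @param fst Balding-Nichols differentiation parameter among subpopulations.
#' @param maf_floor Minimum sample minor allele frequency a polymorphic site
#'   must reach to be kept (0 disables the floor).
#' @param missing_rate Per-call missing-data probability.
#' @param n_blocks,n_reps Blocks and replicates per accession in the
#'   phenotyping design.
#' @param block_sd Block effect standard deviation, ug/g dry weight.
#' @param residual_sd Residual standard deviation used when `true_h2` is not
#'   set on the truth record, ug/g dry weight.
#' @param trait_mean Baseline leaf B content (intercept), ug/g dry weight.
#' @param depth_mean Mean sequencing depth, reads per bp.
#' @param depth_dispersion Negative-binomial overdispersion of depth
#'   (variance = mu + dispersion * mu^2); 0 degenerates to Poisson.
#' @param contamination_rate Fraction of replicate plants receiving a joint
#'   soil-contamination shift on the Cr and Ti channels.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 150, n_variants = 1000, n_subpops = 3,
                       bottleneck_diversity = 1e-3, region_length = 1e5,
                       fst = 0.3, maf_floor = 0, missing_rate = 0.02,
                       n_blocks = 4, n_reps = 4, block_sd = 2,
                       residual_sd = 1, trait_mean = 20,
                       depth_mean = 30, depth_dispersion = 0.1,
                       contamination_rate = 0.02) {
  cfg <- list(
    n_samples = n_samples, n_variants = n_variants, n_subpops = n_subpops,
    bottleneck_diversity = bottleneck_diversity,
    region_length = region_length, fst = fst, maf_floor = maf_floor,
    missing_rate = missing_rate, n_blocks = n_blocks, n_reps = n_reps,
    block_sd = block_sd, residual_sd = residual_sd, trait_mean = trait_mean,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    contamination_rate = contamination_rate
  )
  counts <- c("n_samples", "n_variants", "n_subpops", "n_blocks", "n_reps")
  for (k in counts) {
    if (cfg[[k]] < 1) stop(k, " must be >= 1", call. = FALSE)
  }
  fracs <- c("maf_floor", "missing_rate", "contamination_rate")
  for (k in fracs) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1) {
      stop(k, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$bottleneck_diversity < 0) {
    stop("bottleneck_diversity must be >= 0", call. = FALSE)
  }
  if (cfg$fst <= 0 || cfg$fst >= 1) stop("fst must lie in (0, 1)", call. = FALSE)
  if (cfg$depth_mean < 0) stop("depth_mean must be >= 0", call. = FALSE)
  if (cfg$depth_dispersion < 0) stop("depth_dispersion must be >= 0", call. = FALSE)
  if (cfg$n_subpops > cfg$n_samples) {
    stop("n_subpops exceeds n_samples: invalid config", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Ground-truth record for a simulated dataset
#'
#' Carries everything the generator knows and downstream estimators must
#' recover: causal SNP effects, the causal tandem duplication, the target
#' broad-sense heritability, subpopulation labels and the junction
#' construction truth.
#'
#' @param seed Integer seed the dataset was generated from.
#' @param subpop_labels Named character/factor vector, one label per sample.
#' @param causal_snps Tibble with columns `id` and `effect` (ug/g per copy of
#'   the alternate allele).
#' @param causal_td `NULL` or a list with `start`, `end` (bp), `carriers`
#'   (sample ids) and `effect_per_copy` (ug/g per extra copy).
#' @param true_h2 Target broad-sense heritability in `[0, 1]`, or `NA` to use
#'   the config's `residual_sd` directly.
#' @param junction_truth `NULL` or a [junction_call()].
#' @return A list of class `truth_record`.
#' @export
truth_record <- function(seed = NA_integer_, subpop_labels = character(),
                         causal_snps = tibble::tibble(id = character(),
                                                      effect = double()),
                         causal_td = NULL, true_h2 = NA_real_,
                         junction_truth = NULL) {
  if (!is.na(true_h2) && (true_h2 < 0 || true_h2 > 1)) {
    stop("true_h2 must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(causal_td)) {
    stopifnot(causal_td$start < causal_td$end)
    if (length(subpop_labels) &&
        !all(causal_td$carriers %in% names(subpop_labels))) {
      stop("causal_td carriers must be a subset of sample ids", call. = FALSE)
    }
  }
  structure(
    list(seed = seed, subpop_labels = subpop_labels,
         causal_snps = tibble::as_tibble(causal_snps),
         causal_td = causal_td, true_h2 = true_h2,
         junction_truth = junction_truth),
    class = "truth_record"
  )
}

# Deterministic child seeds so each sub-generator has its own stream.
child_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 7919L) %% 2147483647L

#' Simulate genotypes for a bottlenecked, structured island population
#'
#' Draws a finite-island (Balding-Nichols) population of inbred lines. The
#' number of segregating sites is drawn as Poisson(theta * a_n * L) around
#' the target per-site diversity, so realized Watterson's theta is centred on
#' `bottleneck_diversity` by construction; island-wide allele frequencies
#' follow the neutral 1/i spectrum and subpopulation frequencies are
#' Beta-dispersed around them with differentiation `fst`. Remaining sites up
#' to `n_variants` are monomorphic. Per-call DP and GQ are populated so that
#' quality filters have something to act on.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(config, seed)`.
#' @return A list with elements `geno` (a [geno_matrix()]) and `truth`
#'   (a [truth_record()] carrying subpopulation labels).
#' @export
simulate_island_population <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  set.seed(child_seed(seed, 1L))
  samples <- sprintf("S%03d", seq_len(n))
  subpop <- sort(rep_len(paste0("pop", seq_len(config$n_subpops)), n))
  names(subpop) <- samples

  a_n <- sum(1 / seq_len(n - 1))
  s_target <- if (config$bottleneck_diversity > 0) {
    stats::rpois(1, config$bottleneck_diversity * a_n * config$region_length)
  } else 0L
  s_target <- min(s_target, config$n_variants)

  # island-wide frequencies from the neutral 1/i spectrum; candidate sites
  # are drawn in batches and kept only if segregating in the sample (and
  # above the MAF floor), until the Poisson site target is reached
  spec_w <- 1 / seq_len(n - 1)
  f <- config$fst
  sub_idx <- match(subpop, unique(subpop))
  poly_cols <- list()
  got <- 0L
  rounds <- 0L
  while (got < s_target && rounds < 200L) {
    rounds <- rounds + 1L
    batch <- max(2L * (s_target - got), 20L)
    p0 <- sample.int(n - 1, batch, replace = TRUE, prob = spec_w) / n
    pk <- matrix(
      stats::rbeta(batch * config$n_subpops,
                   rep(p0, each = config$n_subpops) * (1 - f) / f,
                   rep(1 - p0, each = config$n_subpops) * (1 - f) / f),
      nrow = config$n_subpops
    )
    x <- matrix(stats::rbinom(n * batch, 1, pk[sub_idx, , drop = FALSE]),
                nrow = n)
    af <- colMeans(x)
    ok <- af > 0 & af < 1 & pmin(af, 1 - af) >= config$maf_floor
    take <- which(ok)[seq_len(min(sum(ok), s_target - got))]
    if (length(take)) {
      poly_cols[[length(poly_cols) + 1L]] <- x[, take, drop = FALSE]
      got <- got + length(take)
    }
  }
  poly <- if (length(poly_cols)) do.call(cbind, poly_cols)
          else matrix(integer(0), nrow = n, ncol = 0)
  n_poly <- ncol(poly)
  n_mono <- config$n_variants - n_poly
  calls <- cbind(poly, matrix(0L, nrow = n, ncol = n_mono))

  pos <- sort(sample.int(config$region_length, config$n_variants))
  ord <- sample.int(config$n_variants) # interleave mono/poly along the region
  calls <- calls[, ord, drop = FALSE]

  # missingness and per-call quality
  miss <- matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow = n)
  dp <- matrix(stats::rpois(length(calls), config$depth_mean), nrow = n)
  gq <- matrix(30L + stats::rpois(length(calls), 30), nrow = n)
  dp[miss] <- stats::rpois(sum(miss), 1.5)
  gq[miss] <- stats::rpois(sum(miss), 8)
  calls[miss] <- NA_integer_

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_variants, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  variants <- tibble::tibble(
    chrom = "chr1", pos = pos,
    id = paste0("chr1:", pos), ref = ref, alt = unname(alt)
  )
  g <- geno_matrix(calls, variants, samples, dp = dp, gq = gq)
  list(
    geno = g,
    truth = truth_record(seed = as.integer(seed), subpop_labels = subpop)
  )
}

#' Attach causal effects to a truth record
#'
#' @param truth A [truth_record()].
#' @param geno The [geno_matrix()] the ids refer to.
#' @param snp_ids Variant ids to make causal.
#' @param snp_effects Per-allele effects (ug/g DW), recycled against
#'   `snp_ids`.
#' @param td `NULL` or a list `(start, end, carriers, effect_per_copy)`.
#' @param true_h2 Target broad-sense heritability.
#' @return The updated [truth_record()].
#' @export
set_causal_effects <- function(truth, geno, snp_ids = character(),
                               snp_effects = numeric(), td = NULL,
                               true_h2 = truth$true_h2) {
  missing_ids <- setdiff(snp_ids, geno$variants$id)
  if (length(missing_ids)) {
    stop("causal variant id(s) not in genotypes: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  truth$causal_snps <- tibble::tibble(
    id = snp_ids,
    effect = rep_len(snp_effects, length(snp_ids))
  )
  truth$causal_td <- td
  truth$true_h2 <- true_h2
  truth_record(truth$seed, truth$subpop_labels, truth$causal_snps,
               truth$causal_td, truth$true_h2, truth$junction_truth)
}

#' Simulate a replicated, blocked ionome phenotype table
#'
#' Builds leaf B values as intercept + genetic value + block effect +
#' residual under a randomized block design (each accession replicated across
#' blocks), plus Cr and Ti soil-contamination sentinel channels. When
#' `truth$true_h2` is set, the residual variance is solved so that
#' `var_genetic / (var_genetic + var_block + var_residual)` equals it — the
#' quantity a one-way repeatability fit estimates under this design. A
#' fraction `contamination_rate` of replicate plants receives a joint
#' multiplicative shift on Cr and Ti far beyond the |z| = 3 filter.
#'
#' @param geno A [geno_matrix()].
#' @param truth A [truth_record()] with causal effects set.
#' @param config The [sim_config()].
#' @param seed Integer seed.
#' @return An ionome tibble with columns `sample_id`, `accession`, `block`,
#'   `replicate`, `B`, `Cr`, `Ti` (ug/g dry weight).
#' @export
simulate_trait <- function(geno, truth, config, seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_record"))
  set.seed(child_seed(seed, 2L))
  n <- n_samples(geno)
  accessions <- geno$samples

  gval <- rep(0, n)
  if (nrow(truth$causal_snps)) {
    missing_ids <- setdiff(truth$causal_snps$id, geno$variants$id)
    if (length(missing_ids)) {
      stop("causal variant id(s) not in genotypes: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    x <- impute_calls(geno)[, truth$causal_snps$id, drop = FALSE]
    gval <- gval + unname(drop(x %*% truth$causal_snps$effect))
  }
  if (!is.null(truth$causal_td)) {
    extra <- as.numeric(accessions %in% truth$causal_td$carriers)
    gval <- gval + extra * truth$causal_td$effect_per_copy
  }

  var_g <- stats::var(gval)
  block_sd <- config$block_sd
  if (!is.na(truth$true_h2) && var_g > 0 && truth$true_h2 > 0) {
    var_env <- var_g * (1 - truth$true_h2) / truth$true_h2
    var_e <- var_env - block_sd^2
    if (var_e < 0) {
      warning("block_sd too large for requested true_h2; shrinking block variance")
      block_sd <- sqrt(var_env / 2)
      var_e <- var_env - block_sd^2
    }
    resid_sd <- sqrt(var_e)
  } else {
    resid_sd <- config$residual_sd
  }

  design <- tidyr::expand_grid(accession = accessions,
                               replicate = seq_len(config$n_reps))
  design$block <- ((design$replicate - 1L) %% config$n_blocks) + 1L
  # blocks are fixed design effects: centre and rescale the draws so the
  # realized block variance equals block_sd^2 exactly, keeping the promised
  # variance partition free of chi-squared noise from so few block draws
  block_eff <- stats::rnorm(config$n_blocks)
  if (config$n_blocks > 1 && block_sd > 0) {
    block_eff <- (block_eff - mean(block_eff)) / stats::sd(block_eff) * block_sd
  } else {
    block_eff <- rep(0, config$n_blocks)
  }
  m <- nrow(design)
  tab <- tibble::tibble(
    sample_id = paste(design$accession, design$block, design$replicate,
                      sep = "_"),
    accession = design$accession,
    block = paste0("block", design$block),
    replicate = design$replicate,
    B = config$trait_mean + gval[match(design$accession, accessions)] +
      block_eff[design$block] + stats::rnorm(m, 0, resid_sd),
    Cr = stats::rlnorm(m, log(0.5), 0.3),
    Ti = stats::rlnorm(m, log(2), 0.3)
  )
  contam <- stats::runif(m) < config$contamination_rate
  tab$Cr[contam] <- tab$Cr[contam] * 15
  tab$Ti[contam] <- tab$Ti[contam] * 15
  tab$B <- pmax(tab$B, 0)
  attr(tab, "contaminated") <- tab$sample_id[contam]
  tab
}

#' Per-base depth profile over a (possibly duplicated) region
#'
#' @param chrom Chromosome label.
#' @param start,end 0-based half-open bounds.
#' @param depth Integer vector of per-base read counts, length `end - start`.
#' @return A list of class `depth_profile`.
#' @export
depth_profile <- function(chrom, start, end, depth) {
  stopifnot(start >= 0, end > start, length(depth) == end - start,
            all(depth >= 0))
  structure(list(chrom = chrom, start = start, end = end,
                 depth = as.numeric(depth)),
            class = "depth_profile")
}

#' Simulate read depth over a region containing a tandem duplication
#'
#' Expected depth is `depth_mean * copies` inside `[start, end)` and
#' `depth_mean` outside; counts are negative binomial with variance
#' `mu + dispersion * mu^2` (Poisson when `dispersion = 0`).
#'
#' @param region_length Region length in bp.
#' @param duplication Numeric triple `(start, end, copies)`; 0-based
#'   half-open, `copies = 1` means no duplication.
#' @param depth_mean Mean haploid depth, reads/bp.
#' @param dispersion Non-negative overdispersion.
#' @param seed Integer seed.
#' @return A [depth_profile()].
#' @export
simulate_depth_profile <- function(region_length, duplication,
                                   depth_mean = 30, dispersion = 0,
                                   seed = 1L) {
  if (depth_mean < 0) stop("depth_mean must be >= 0: invalid config", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0: invalid config", call. = FALSE)
  start <- duplication[[1]]; end <- duplication[[2]]; copies <- duplication[[3]]
  stopifnot(start >= 0, start < end, end <= region_length, copies >= 1)
  set.seed(child_seed(seed, 3L))
  mu <- rep(depth_mean, region_length)
  mu[(start + 1L):end] <- depth_mean * copies
  depth <- if (dispersion == 0) {
    stats::rpois(region_length, mu)
  } else {
    stats::rnbinom(region_length, mu = mu, size = 1 / dispersion)
  }
  depth_profile("chr2", 0L, region_length, depth)
}

#' Breakpoint junction call
#'
#' @param type One of `"blunt"`, `"microhomology"`, `"insertion"`.
#' @param length Homology or insert length in bp (0 for blunt).
#' @param sequence Homology motif or inserted sequence (`""` for blunt).
#' @return A list of class `junction_call`.
#' @export
junction_call <- function(type = c("blunt", "microhomology", "insertion"),
                          length = 0L, sequence = "") {
  type <- match.arg(type)
  if (type == "blunt") {
    stopifnot(length == 0L, sequence == "")
  } else {
    stopifnot(length >= 1L, nchar(sequence) == length)
  }
  structure(list(type = type, length = as.integer(length),
                 sequence = toupper(sequence)),
            class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("<junction_call> %s (%d bp)%s\n", x$type, x$length,
              if (nzchar(x$sequence)) paste0(" ", x$sequence) else ""))
  invisible(x)
}

#' Random nucleotide reference sequence
#'
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @return A single upper-case character string over A/C/G/T.
#' @export
random_reference <- function(length, seed = 1L) {
  set.seed(child_seed(seed, 4L))
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

subseq_chr <- function(s, from, to) substr(s, from, to)

replace_at <- function(s, from, replacement) {
  paste0(substr(s, 1, from - 1), replacement,
         substr(s, from + nchar(replacement), nchar(s)))
}

#' Construct a tandem-duplication junction sequence with known truth
#'
#' Builds the junction-spanning sequence of a tandem duplication of
#' `reference[dup_start..dup_end]` (1-based, inclusive). For a blunt junction
#' the read is the last `flank_len` bases of copy 1 followed directly by the
#' first `flank_len` bases of copy 2; for an insertion the novel sequence sits
#' between them. Microhomology is imposed as a property of the reference: the
#' constructor edits it so the `k`-base motif both ends copy 1 (at `dup_end`)
#' and starts copy 2 (at `dup_start`), and the junction read then carries the
#' motif exactly once — repair annealed the two ends over the shared motif —
#' so the copy-2 context in the read begins at `dup_start + k`. This is the
#' alignment-overlap signature a junction classifier recovers.
#'
#' @param reference Reference sequence (character string).
#' @param dup_start,dup_end 1-based inclusive bounds of the duplicated
#'   segment.
#' @param type `"blunt"`, `"microhomology"` or `"insertion"`.
#' @param motif Homology motif (required for `"microhomology"`); its length
#'   is the homology length `k`. Must satisfy `2k < dup length` so the two
#'   reference edits cannot collide.
#' @param insert Inserted sequence (required for `"insertion"`).
#' @param flank_len Context length carried on each side of the junction.
#' @return A list with `junction` (the junction-spanning sequence),
#'   `reference` (the possibly edited reference), `dup_start`, `dup_end`, and
#'   `truth` (a [junction_call()]).
#' @export
make_junction_sequence <- function(reference, dup_start, dup_end,
                                   type = c("blunt", "microhomology",
                                            "insertion"),
                                   motif = NULL, insert = NULL,
                                   flank_len = 50L) {
  type <- match.arg(type)
  reference <- toupper(reference)
  L <- nchar(reference)
  stopifnot(dup_start >= 1, dup_end <= L, dup_start < dup_end,
            dup_end - flank_len + 1 >= 1, dup_start + flank_len - 1 <= L)
  dup_len <- dup_end - dup_start + 1L
  k <- 0L

  truth <- switch(
    type,
    blunt = junction_call("blunt", 0L, ""),
    microhomology = {
      if (is.null(motif)) stop("motif is required for microhomology", call. = FALSE)
      motif <- toupper(motif)
      k <- nchar(motif)
      if (2L * k >= dup_len) {
        stop("homology length k too long relative to the duplication",
             call. = FALSE)
      }
      if (dup_start + k + flank_len - 1L > L) {
        stop("reference too short for flank context past the homology",
             call. = FALSE)
      }
      reference <- replace_at(reference, dup_end - k + 1L, motif)
      reference <- replace_at(reference, dup_start, motif)
      junction_call("microhomology", k, motif)
    },
    insertion = {
      if (is.null(insert) || !nzchar(insert)) {
        stop("insert sequence is required for insertion", call. = FALSE)
      }
      junction_call("insertion", nchar(insert), toupper(insert))
    }
  )

  ins <- if (type == "insertion") toupper(insert) else ""
  junction <- paste0(
    subseq_chr(reference, dup_end - flank_len + 1L, dup_end),
    ins,
    subseq_chr(reference, dup_start + k, dup_start + k + flank_len - 1L)
  )
  list(junction = junction, reference = reference,
       dup_start = dup_start, dup_end = dup_end, truth = truth)
}
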