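#' Default pipeline configuration
#'
#' Returns the full configuration tree with every threshold at its
#' documented default: z-score cut 3 and replicate floor 3 for phenotype QC;
#' MAF >= 0.05, missingness < 0.10, DP > 3 and GQ > 20 for the association
#' scan with 5% Bonferroni and 10% FDR thresholds; 800 bp windows every
#' 400 bp with 3 kb flanks for copy-number genotyping; mu0 = 7e-9, 5%
#' outcrossing and 10 Mb / 50 kb rate windows for the population-genetic
#' stage.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    stages = c("simulate", "qc", "gwas", "cnv", "popgen"),
    out_dir = NULL,
    sim = list(
      n_samples = 200L, n_variants = 500L, n_subpops = 3L,
      bottleneck_diversity = 1e-3, region_length = 1e5, fst = 0.3,
      maf_floor = 0, missing_rate = 0.02, n_blocks = 4L, n_reps = 4L,
      block_sd = 2, residual_sd = 1, trait_mean = 20, depth_mean = 30,
      depth_dispersion = 0.1, contamination_rate = 0.02
    ),
    causal = list(n_snps = 1L, effect = 8, target_maf = 0.3, true_h2 = 0.75),
    qc = list(z_threshold = 3, min_reps = 3L,
              channels = c("B", "Cr", "Ti")),
    gwas = list(maf_min = 0.05, miss_max = 0.10, dp_min = 3, gq_min = 20,
                alpha = 0.05, fdr_q = 0.10, condition = character()),
    cnv = list(window = 800L, step = 400L, flank = 3000L,
               ratio_threshold = 1.5, min_run = 3L,
               region_length = 60000L, dup_start = 15000L,
               dup_end = 45000L, dup_copies = 2L, depth_mean = 30,
               depth_dispersion = 0, junction_type = "microhomology",
               junction_motif = "TACATA", junction_insert = NULL,
               flank_probe = 50L),
    popgen = list(mu0 = 7e-9, outcrossing = 0.05, dp_min = 3, gq_min = 25,
                  rate_window = 10e6, rate_step = 50e3, cm_per_mb = 4)
  ), class = "pipeline_config")
}

config_domains <- list(
  "qc.z_threshold" = c(0, Inf), "qc.min_reps" = c(1, Inf),
  "gwas.maf_min" = c(0, 0.5), "gwas.miss_max" = c(0, 1),
  "gwas.dp_min" = c(0, Inf), "gwas.gq_min" = c(0, Inf),
  "gwas.alpha" = c(0, 1), "gwas.fdr_q" = c(0, 1),
  "cnv.window" = c(1, Inf), "cnv.step" = c(1, Inf),
  "cnv.flank" = c(1, Inf), "cnv.ratio_threshold" = c(1, Inf),
  "cnv.min_run" = c(1, Inf),
  "popgen.mu0" = c(0, 1), "popgen.outcrossing" = c(1e-12, 1),
  "popgen.dp_min" = c(0, Inf), "popgen.gq_min" = c(0, Inf),
  "popgen.rate_window" = c(1, Inf), "popgen.rate_step" = c(1, Inf)
)

#' Validate and complete a pipeline configuration
#'
#' Merges a partial configuration (a nested list, or the path of a YAML
#' file) into [default_config()]. Unknown keys are rejected; numeric
#' thresholds are checked against their documented domains with an error
#' naming the key and allowed range; every deviation from a default is
#' reported via `message()` so a run log records the effective settings.
#'
#' @param raw A nested list, a YAML file path, or `NULL` for pure defaults.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(raw = NULL) {
  cfg <- default_config()
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) return(cfg)
  stopifnot(is.list(raw))

  merge_level <- function(base, upd, path = character()) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste(c(path, unknown[1]), collapse = "."), call. = FALSE)
    }
    for (k in names(upd)) {
      if (is.list(base[[k]]) && is.list(upd[[k]]) &&
          !is.null(names(base[[k]]))) {
        base[[k]] <- merge_level(base[[k]], upd[[k]], c(path, k))
      } else {
        key <- paste(c(path, k), collapse = ".")
        new <- upd[[k]]
        dom <- config_domains[[key]]
        if (!is.null(dom) && (!is.numeric(new) || new < dom[1] || new > dom[2])) {
          stop(sprintf("config key %s = %s outside allowed range [%g, %g]",
                       key, toString(new), dom[1], dom[2]), call. = FALSE)
        }
        if (!identical(as.vector(new), as.vector(base[[k]]))) {
          message(sprintf("config: %s = %s (default %s)", key,
                          toString(new), toString(base[[k]])))
        }
        base[[k]] <- new
      }
    }
    base
  }
  out <- merge_level(unclass(cfg), raw)
  structure(out, class = "pipeline_config")
}

pick_causal_variants <- function(g, n_snps, target_maf) {
  st <- variant_stats(g)
  # missing calls at the causal site are mean-imputed downstream, so only
  # polymorphism matters here
  poly <- st[!is.na(st$maf) & st$maf > 0, ]
  if (nrow(poly) < n_snps) stop("not enough polymorphic variants for causal assignment",
                                call. = FALSE)
  poly$id[order(abs(poly$maf - target_maf), poly$pos)][seq_len(n_snps)]
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order — simulate, phenotype QC and BLUEs,
#' kinship-corrected association scan, depth-based copy-number and junction
#' genotyping, population-genetic preprocessing — writing each stage's
#' tables under `out_dir` along with a machine-readable run manifest
#' (seed, configuration hash, record counts). The whole run is a pure
#' function of the configuration: identical config and seed give identical
#' outputs.
#'
#' @param config A `pipeline_config` from [validate_config()], or a raw
#'   list/YAML path to be validated.
#' @return A list with per-stage results (`truth`, `geno`, `pheno`,
#'   `blues`, `h2`, `scan`, `cn`, `junction`, `popgen`), the `manifest`,
#'   and `paths` of all written files.
#' @export
run_pipeline <- function(config = default_config()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  stages <- config$stages
  known <- c("simulate", "qc", "gwas", "cnv", "popgen")
  stopifnot(all(stages %in% known))
  # stage-input dependencies checked up front, before any compute
  if ("qc" %in% stages && !"simulate" %in% stages) {
    stop("qc stage requires the simulate stage (no phenotype input)", call. = FALSE)
  }
  if ("gwas" %in% stages && !all(c("simulate", "qc") %in% stages)) {
    stop("gwas stage requires simulate and qc stages", call. = FALSE)
  }
  if ("popgen" %in% stages && !"simulate" %in% stages) {
    stop("popgen stage requires the simulate stage", call. = FALSE)
  }

  out_dir <- config$out_dir %||% tempfile("tdgwas_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  paths <- list()
  results <- list()
  counts <- list()

  # --- simulate ------------------------------------------------------------
  sim_cfg <- do.call(sim_config, config$sim)
  pop <- simulate_island_population(sim_cfg, seed)
  g <- pop$geno
  truth <- pop$truth
  if (config$causal$n_snps > 0) {
    ids <- pick_causal_variants(g, config$causal$n_snps,
                                config$causal$target_maf)
    truth <- set_causal_effects(truth, g, snp_ids = ids,
                                snp_effects = config$causal$effect,
                                true_h2 = config$causal$true_h2)
  }
  pheno <- simulate_trait(g, truth, sim_cfg, seed)
  paths$vcf <- file.path(out_dir, "genotypes.vcf")
  paths$pheno <- file.path(out_dir, "phenotypes.tsv")
  paths$truth <- file.path(out_dir, "truth.yaml")
  write_vcf(g, paths$vcf)
  write_pheno_tsv(pheno, paths$pheno)
  write_truth_yaml(truth, paths$truth)
  results$geno <- g; results$truth <- truth; results$pheno <- pheno
  counts$simulate <- c(samples = n_samples(g), variants = n_variants(g),
                       pheno_rows = nrow(pheno))
  if (!"qc" %in% stages && !"gwas" %in% stages &&
      !"cnv" %in% stages && !"popgen" %in% stages) {
    results$manifest <- write_manifest(config, out_dir, counts)
    results$paths <- paths
    return(results)
  }

  # --- qc ------------------------------------------------------------------
  if ("qc" %in% stages) {
    qc1 <- zscore_outlier_filter(pheno, channels = config$qc$channels,
                                 threshold = config$qc$z_threshold)
    qc2 <- min_replicate_filter(qc1, min_reps = config$qc$min_reps)
    blues <- compute_blues(qc2, element = "B")
    h2 <- broad_sense_heritability(qc2, element = "B")
    paths$blues <- file.path(out_dir, "blues.tsv")
    readr::write_tsv(blues, paths$blues)
    results$blues <- blues; results$h2 <- h2
    counts$qc <- c(rows_in = nrow(pheno), rows_after_z = nrow(qc1),
                   rows_after_floor = nrow(qc2),
                   accessions = nrow(blues))
  }

  # --- gwas ----------------------------------------------------------------
  if ("gwas" %in% stages) {
    gf <- filter_genotypes(g, dp_min_exclusive = config$gwas$dp_min,
                           gq_min_exclusive = config$gwas$gq_min)
    gf <- filter_variants(gf, maf_min = config$gwas$maf_min,
                          miss_max = config$gwas$miss_max)
    keep <- gf$samples %in% results$blues$accession
    gf <- gf[which(keep), ]
    k <- centered_kinship(gf)
    scan <- if (length(config$gwas$condition)) {
      conditional_scan(gf, results$blues, k = k,
                       lead_markers = config$gwas$condition,
                       alpha = config$gwas$alpha, fdr_q = config$gwas$fdr_q)
    } else {
      lmm_scan(gf, results$blues, k = k,
               alpha = config$gwas$alpha, fdr_q = config$gwas$fdr_q)
    }
    paths$scan <- file.path(out_dir, "association.tsv")
    paths$scan_summary <- file.path(out_dir, "association_summary.tsv")
    readr::write_tsv(tidy(scan), paths$scan)
    readr::write_tsv(glance(scan), paths$scan_summary)
    results$scan <- scan
    counts$gwas <- c(variants_tested = scan$n_tests,
                     samples = scan$n_samples)
  }

  # --- cnv -----------------------------------------------------------------
  if ("cnv" %in% stages) {
    cc <- config$cnv
    prof_dup <- simulate_depth_profile(
      cc$region_length, c(cc$dup_start, cc$dup_end, cc$dup_copies),
      depth_mean = cc$depth_mean, dispersion = cc$depth_dispersion,
      seed = child_seed(seed, 11L)
    )
    prof_ref <- simulate_depth_profile(
      cc$region_length, c(cc$dup_start, cc$dup_end, 1),
      depth_mean = cc$depth_mean, dispersion = cc$depth_dispersion,
      seed = child_seed(seed, 12L)
    )
    cn_dup <- estimate_cn(prof_dup, c(cc$dup_start, cc$dup_end),
                          window = cc$window, step = cc$step,
                          flank = cc$flank)
    cn_ref <- estimate_cn(prof_ref, c(cc$dup_start, cc$dup_end),
                          window = cc$window, step = cc$step,
                          flank = cc$flank)
    ref_seq <- random_reference(2L * cc$flank_probe + 2000L,
                                seed = child_seed(seed, 13L))
    jx <- make_junction_sequence(
      ref_seq, dup_start = 200L, dup_end = 1800L,
      type = cc$junction_type, motif = cc$junction_motif,
      insert = cc$junction_insert, flank_len = cc$flank_probe
    )
    jcall <- classify_junction(jx$junction, jx$reference, jx$dup_start,
                               jx$dup_end, flank_probe = cc$flank_probe)
    cn_tab <- dplyr::bind_rows(
      dplyr::mutate(glance(cn_dup), sample = "carrier", .before = 1),
      dplyr::mutate(glance(cn_ref), sample = "non_carrier", .before = 1)
    )
    paths$cn <- file.path(out_dir, "cn_calls.tsv")
    paths$junction_report <- file.path(out_dir, "junctions.tsv")
    paths$junction_fasta <- file.path(out_dir, "junction.fasta")
    paths$depth <- file.path(out_dir, "depth_carrier.tsv")
    readr::write_tsv(cn_tab, paths$cn)
    readr::write_tsv(tidy(jcall), paths$junction_report)
    write_fasta(c(junction = jx$junction), paths$junction_fasta)
    write_depth_tsv(prof_dup, paths$depth)
    results$cn <- cn_tab
    results$junction <- jcall
    counts$cnv <- c(cn_carrier = cn_dup$cn, cn_non_carrier = cn_ref$cn)
  }

  # --- popgen --------------------------------------------------------------
  if ("popgen" %in% stages) {
    pg <- config$popgen
    theta <- watterson_theta(g, sim_cfg$region_length)
    rates <- corrected_mutation_rate(g, window = pg$rate_window,
                                     step = pg$rate_step, mu0 = pg$mu0,
                                     dp_min = pg$dp_min, gq_min = pg$gq_min)
    raw_map <- tibble::tibble(
      pos = c(1L, as.integer(sim_cfg$region_length)),
      cm = c(0, pg$cm_per_mb * sim_cfg$region_length / 1e6)
    )
    scaled_map <- scale_recombination_map(raw_map,
                                          outcrossing_rate = pg$outcrossing)
    hap_freq <- if (nrow(truth$causal_snps)) {
      carriers <- impute_calls(g)[, truth$causal_snps$id[1]] >= 0.5
      haplotype_frequency_by_subpop(as.numeric(carriers),
                                    truth$subpop_labels)
    }
    paths$rates <- file.path(out_dir, "mutation_rates.tsv")
    paths$map <- file.path(out_dir, "scaled_map.tsv")
    readr::write_tsv(rates, paths$rates)
    readr::write_tsv(scaled_map, paths$map)
    bundle <- export_genealogy_inputs(
      g, scaled_map, file.path(out_dir, "genealogy"),
      dp_min = pg$dp_min, gq_min = pg$gq_min
    )
    paths <- c(paths, bundle)
    results$popgen <- list(theta_w = theta, rates = rates,
                           scaled_map = scaled_map, hap_freq = hap_freq)
    counts$popgen <- c(theta_w = theta)
  }

  results$manifest <- write_manifest(config, out_dir, counts)
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  results$paths <- paths
  results
}

write_manifest <- function(config, out_dir, counts) {
  manifest <- list(
    package = "tdgwas",
    version = as.character(utils::packageVersion("tdgwas")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = as.list(config$stages),
    counts = lapply(counts, as.list)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}
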