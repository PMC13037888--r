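#' Watterson's theta per site
#'
#' `theta_w = S / (a_n * L)` where `S` is the number of segregating sites
#' observed among the sampled haplotypes, `a_n = sum_{i=1}^{n-1} 1/i`, and
#' `L` is the surveyed region length in bp. Inbred accessions contribute one
#' haplotype each, so `n` is the number of samples. A site counts as
#' segregating when both alleles are observed among its non-missing calls.
#'
#' @param g A [geno_matrix()] of haploid-coded calls.
#' @param region_length Surveyed length `L` in bp.
#' @return Per-site theta (a scalar).
#' @export
watterson_theta <- function(g, region_length) {
  n <- n_samples(g)
  if (n < 2) stop("need at least 2 haploid sequences", call. = FALSE)
  if (region_length <= 0) stop("region_length must be positive", call. = FALSE)
  st <- variant_stats(g)
  s <- sum(!is.na(st$maf) & st$maf > 0)
  a_n <- sum(1 / seq_len(n - 1))
  s / (a_n * region_length)
}

#' Missingness-corrected mutation rate in sliding windows
#'
#' Scales a spontaneous per-bp per-generation mutation rate `mu0` by the
#' fraction of usable variants in sliding windows:
#' `mu_corrected = mu0 * (1 - missing / total)`. `total` counts biallelic
#' SNPs whose missing-call fraction is at most `miss_max`; `missing` counts
#' those among them that still fail the completeness rule — any absent call,
#' or any call with DP not above `dp_min` or GQ not above `gq_min`. Windows
#' are truncated at the chromosome end; a window with no eligible variants
#' reports a missing rate.
#'
#' @param g A [geno_matrix()] carrying per-call DP and GQ.
#' @param window Window size in bp (default 10 Mb).
#' @param step Step size in bp (default 50 kb).
#' @param mu0 Uncorrected spontaneous mutation rate (default 7e-9).
#' @param dp_min,gq_min Exclusive completeness cuts (DP > 3, GQ > 25).
#' @param miss_max Maximum missing-call fraction for a variant to be
#'   eligible at all (default 0.10).
#' @return A tibble with columns `chrom`, `window_start`, `window_end`,
#'   `total_variants`, `missing_variants`, `mu_corrected`.
#' @export
corrected_mutation_rate <- function(g, window = 10e6, step = 50e3,
                                    mu0 = 7e-9, dp_min = 3, gq_min = 25,
                                    miss_max = 0.10) {
  stopifnot(window >= step, step >= 1, mu0 > 0)
  st <- variant_stats(g)
  eligible <- st$miss <= miss_max
  complete <- vapply(seq_len(n_variants(g)), function(j) {
    calls <- g$calls[, j]
    if (anyNA(calls)) return(FALSE)
    dp_ok <- is.null(g$dp) || all(g$dp[, j] > dp_min)
    gq_ok <- is.null(g$gq) || all(g$gq[, j] > gq_min)
    dp_ok && gq_ok
  }, logical(1))

  purrr::map_dfr(split(seq_len(n_variants(g)), st$chrom), function(idx) {
    pos <- st$pos[idx]
    chrom_end <- max(pos)
    starts <- seq(1, chrom_end, by = step)
    ends <- pmin(starts + window - 1, chrom_end)
    purrr::map_dfr(seq_along(starts), function(w) {
      inw <- idx[pos >= starts[w] & pos <= ends[w]]
      tot <- sum(eligible[inw])
      mis <- sum(eligible[inw] & !complete[inw])
      tibble::tibble(
        chrom = st$chrom[idx[1]],
        window_start = starts[w], window_end = ends[w],
        total_variants = tot, missing_variants = mis,
        mu_corrected = if (tot == 0) NA_real_ else mu0 * (1 - mis / tot)
      )
    })
  })
}

#' Scale a recombination map by the outcrossing rate
#'
#' Predominantly selfing populations experience effective recombination only
#' in the rare outcrossed generations, so genetic distances are multiplied
#' by the outcrossing fraction (equivalently divided by its reciprocal; a 5%
#' outcrossing rate divides distances by twenty).
#'
#' @param map Tibble with columns `pos` (bp, strictly increasing) and `cm`
#'   (cumulative genetic distance, non-decreasing).
#' @param outcrossing_rate Outcrossing fraction in (0, 1] (default 0.05).
#' @return The map with `cm` rescaled.
#' @export
scale_recombination_map <- function(map, outcrossing_rate = 0.05) {
  stopifnot(all(c("pos", "cm") %in% names(map)))
  if (outcrossing_rate <= 0 || outcrossing_rate > 1) {
    stop("outcrossing_rate must lie in (0, 1]", call. = FALSE)
  }
  if (any(diff(map$pos) <= 0)) stop("map positions must increase", call. = FALSE)
  if (any(diff(map$cm) < 0)) stop("genetic distances must be non-decreasing",
                                  call. = FALSE)
  dplyr::mutate(map, cm = .data$cm * outcrossing_rate)
}

#' Haplotype carrier frequencies by subpopulation
#'
#' Counts carriers of a haplotype (e.g. a tandem duplication) within each
#' subpopulation and flags haplotypes private to a single subpopulation.
#'
#' @param carriers Named 0/1 vector: 1 for carrier samples.
#' @param labels Subpopulation label per sample (same order/names).
#' @return A tibble with columns `subpop`, `n_samples`, `carrier_count`,
#'   `frequency` and `private` (`TRUE` on the single subpopulation holding
#'   all carriers, if there is one).
#' @export
haplotype_frequency_by_subpop <- function(carriers, labels) {
  stopifnot(length(carriers) == length(labels))
  tab <- tibble::tibble(carrier = as.numeric(carriers),
                        subpop = as.character(labels)) |>
    dplyr::group_by(.data$subpop) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      carrier_count = sum(.data$carrier),
      frequency = mean(.data$carrier),
      .groups = "drop"
    )
  with_carriers <- tab$subpop[tab$carrier_count > 0]
  tab$private <- tab$carrier_count > 0 & length(with_carriers) == 1
  tab
}

#' Export haps/sample/map genealogy-inference inputs
#'
#' Writes the SHAPEIT-style file bundle consumed by haploid genealogy
#' inference: one row per site in the `.haps` file (chrom, id, pos, ref,
#' alt, then one allele column per inbred line), a `.sample` file, a
#' `.map` file (position, rate in cM/Mb, cumulative cM), and a
#' `.poplabels` file separating ingroup from outgroup samples. Sites must
#' pass the completeness rule (biallelic, no missing call, all DP > `dp_min`
#' and GQ > `gq_min`); tandem-duplication breakpoints enter as biallelic
#' pseudo-variants coded 1 for carrier lines. A pseudo-variant colliding
#' with an existing position is an error naming the position.
#'
#' @param g A [geno_matrix()].
#' @param map Recombination map tibble (`pos`, `cm`), already scaled.
#' @param prefix Output path prefix (files `<prefix>.haps` etc.).
#' @param breakpoint_pseudovariants List of `list(pos =, carriers =)`
#'   entries, one per tandem-duplication breakpoint.
#' @param outgroup_samples Sample ids labelled as outgroup in
#'   `.poplabels`.
#' @param dp_min,gq_min Exclusive completeness cuts (defaults DP > 3,
#'   GQ > 25).
#' @return Invisibly, a named list of the four file paths.
#' @export
export_genealogy_inputs <- function(g, map, prefix,
                                    breakpoint_pseudovariants = list(),
                                    outgroup_samples = character(),
                                    dp_min = 3, gq_min = 25) {
  complete <- vapply(seq_len(n_variants(g)), function(j) {
    calls <- g$calls[, j]
    if (anyNA(calls)) return(FALSE)
    dp_ok <- is.null(g$dp) || all(g$dp[, j] > dp_min)
    gq_ok <- is.null(g$gq) || all(g$gq[, j] > gq_min)
    dp_ok && gq_ok
  }, logical(1))
  keep <- which(complete)
  v <- g$variants[keep, , drop = FALSE]
  calls <- g$calls[, keep, drop = FALSE]

  rows <- tibble::tibble(
    chrom = v$chrom, id = v$id, pos = v$pos, ref = v$ref, alt = v$alt,
    alleles = lapply(seq_len(nrow(v)), function(j) calls[, j])
  )
  if (length(breakpoint_pseudovariants)) {
    pv_pos <- vapply(breakpoint_pseudovariants, function(p) p$pos, numeric(1))
    if (anyDuplicated(pv_pos)) {
      stop("duplicate pseudo-variant positions", call. = FALSE)
    }
    clash <- intersect(pv_pos, rows$pos)
    if (length(clash)) {
      stop("pseudo-variant collides with existing position ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
    pv_rows <- purrr::map_dfr(breakpoint_pseudovariants, function(p) {
      bad <- setdiff(p$carriers, g$samples)
      if (length(bad)) {
        stop("unknown carrier sample(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      tibble::tibble(
        chrom = rows$chrom[1] %||% "chr1",
        id = paste0("TD:", p$pos), pos = p$pos, ref = "N", alt = "<DUP>",
        alleles = list(as.integer(g$samples %in% p$carriers))
      )
    })
    rows <- dplyr::arrange(dplyr::bind_rows(rows, pv_rows), .data$pos)
  }

  haps_path <- paste0(prefix, ".haps")
  sample_path <- paste0(prefix, ".sample")
  map_path <- paste0(prefix, ".map")
  pop_path <- paste0(prefix, ".poplabels")

  haps_lines <- vapply(seq_len(nrow(rows)), function(i) {
    paste(c(rows$chrom[i], rows$id[i], rows$pos[i], rows$ref[i], rows$alt[i],
            rows$alleles[[i]]), collapse = " ")
  }, character(1))
  writeLines(haps_lines, haps_path)

  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(g$samples, g$samples, 0)), sample_path)

  rate <- c(diff(map$cm) / (diff(map$pos) / 1e6), 0)
  writeLines(c("pos COMBINED_rate Genetic_Map",
               paste(map$pos, rate, map$cm)), map_path)

  grp <- ifelse(g$samples %in% outgroup_samples, "outgroup", "ingroup")
  writeLines(c("sample population group sex",
               paste(g$samples, grp, grp, "NA")), pop_path)

  invisible(list(haps = haps_path, sample = sample_path, map = map_path,
                 poplabels = pop_path))
}

#' Read a haps/sample bundle back
#'
#' Inverse of [export_genealogy_inputs()] for round-trip checks: parses the
#' `.haps` and `.sample` files into a site table and a samples-by-sites
#' allele matrix.
#'
#' @param prefix Path prefix used at export time.
#' @return A list with `sites` (tibble: chrom, id, pos, ref, alt),
#'   `samples` and `alleles` (samples x sites integer matrix).
#' @export
read_genealogy_inputs <- function(prefix) {
  haps <- utils::read.table(paste0(prefix, ".haps"),
                            colClasses = "character")
  smp <- utils::read.table(paste0(prefix, ".sample"), header = TRUE,
                           colClasses = "character")[-1, , drop = FALSE]
  sites <- tibble::tibble(
    chrom = haps[[1]], id = haps[[2]], pos = as.integer(haps[[3]]),
    ref = haps[[4]], alt = haps[[5]]
  )
  alleles <- t(apply(as.matrix(haps[, -(1:5), drop = FALSE]), 1, as.integer))
  if (nrow(sites) == 1L) alleles <- matrix(alleles, nrow = 1L)
  alleles <- t(alleles) # samples x sites
  rownames(alleles) <- smp$ID_1
  colnames(alleles) <- sites$id
  list(sites = sites, samples = smp$ID_1, alleles = alleles)
}
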