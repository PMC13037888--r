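#' Remove soil-contaminated replicate plants by z-score
#'
#' Computes, once over all input rows, the z-score of each listed element
#' channel (sample mean and n-1 SD) and removes any replicate plant whose
#' absolute z-score exceeds `threshold` on any channel. The filter is a
#' single pass: z-scores are not recomputed after removal. A channel whose
#' values are all equal has zero SD and contributes z = 0.
#'
#' @param table Ionome tibble with one row per replicate plant (columns
#'   `sample_id`, `accession`, `block`, `replicate`, plus element channels).
#' @param channels Element columns to screen (default B plus the Cr/Ti
#'   contamination sentinels).
#' @param threshold Absolute z-score cut (default 3).
#' @return The filtered tibble.
#' @export
zscore_outlier_filter <- function(table, channels = c("B", "Cr", "Ti"),
                                  threshold = 3) {
  stopifnot(nrow(table) >= 2, all(channels %in% names(table)))
  z <- vapply(channels, function(ch) {
    x <- table[[ch]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }, numeric(nrow(table)))
  keep <- rowSums(abs(z) > threshold) == 0
  table[keep, , drop = FALSE]
}

#' Drop accessions left with too few replicates
#'
#' @param table Ionome tibble (after [zscore_outlier_filter()]).
#' @param min_reps Minimum surviving replicates per accession (default 3).
#' @return The tibble with under-replicated accessions removed entirely.
#' @export
min_replicate_filter <- function(table, min_reps = 3) {
  dplyr::filter(dplyr::group_by(table, .data$accession),
                dplyr::n() >= min_reps) |>
    dplyr::ungroup()
}

#' Best linear unbiased estimates of accession means
#'
#' Collapses replicated measurements to one value per accession while
#' accounting for block effects: fits
#' `value ~ 0 + accession + (1 | block)` by REML (accession fixed, block
#' random) and returns the accession fixed effects on the original ug/g
#' scale. With a single block, or when the mixed fit is inestimable, the
#' function warns and falls back to ordinary least squares with block as a
#' sum-contrast fixed effect (which reduces to plain accession means when
#' only one block exists).
#'
#' @param table Ionome tibble.
#' @param element Channel to collapse (default `"B"`).
#' @return A tibble with columns `accession`, `blue` (ug/g DW) and
#'   `n_reps_used`.
#' @export
compute_blues <- function(table, element = "B") {
  stopifnot(element %in% names(table))
  df <- data.frame(
    value = table[[element]],
    accession = factor(table$accession),
    block = factor(table$block)
  )
  n_used <- dplyr::count(table, .data$accession, name = "n_reps_used")

  blues <- NULL
  if (nlevels(df$block) >= 2) {
    fit <- tryCatch(
      lme4::lmer(value ~ 0 + accession + (1 | block), data = df, REML = TRUE),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      b <- lme4::fixef(fit)
      blues <- tibble::tibble(
        accession = sub("^accession", "", names(b)),
        blue = unname(b)
      )
    } else {
      warning("mixed-model BLUE fit failed (confounded design); ",
              "falling back to least squares with block fixed")
    }
  } else {
    warning("single block: block effect not identifiable; ",
            "BLUEs are replicate means")
  }
  if (is.null(blues)) {
    form <- if (nlevels(df$block) >= 2) value ~ 0 + accession + block
            else value ~ 0 + accession
    contr <- if (nlevels(df$block) >= 2) list(block = "contr.sum") else NULL
    fit <- stats::lm(form, data = df, contrasts = contr)
    b <- stats::coef(fit)
    b <- b[grepl("^accession", names(b))]
    blues <- tibble::tibble(
      accession = sub("^accession", "", names(b)),
      blue = unname(b)
    )
  }
  dplyr::left_join(blues, n_used, by = "accession")
}

#' Broad-sense heritability from replicate repeatability
#'
#' Fits a one-way random-effects model (`value ~ (1 | accession)`) by REML
#' and reports `H2 = var_line / (var_line + var_residual)`, the fraction of
#' phenotypic variance attributable to differences among lines. Variance
#' components are truncated at zero; a table with no variation at all gives
#' `h2 = 0` with both components zero.
#'
#' @param table Ionome tibble with replicated accessions.
#' @param element Channel to analyse (default `"B"`).
#' @return An object of class `h2_estimate`: a list with `h2`, `var_line`
#'   and `var_residual` ((ug/g)^2).
#' @export
broad_sense_heritability <- function(table, element = "B") {
  stopifnot(element %in% names(table))
  y <- table[[element]]
  if (stats::var(y) == 0) {
    return(structure(list(h2 = 0, var_line = 0, var_residual = 0),
                     class = "h2_estimate"))
  }
  df <- data.frame(value = y, accession = factor(table$accession))
  fit <- lme4::lmer(value ~ (1 | accession), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_line <- max(0, vc$vcov[vc$grp == "accession"])
  var_res <- max(0, vc$vcov[vc$grp == "Residual"])
  h2 <- if (var_line + var_res == 0) 0 else var_line / (var_line + var_res)
  structure(list(h2 = h2, var_line = var_line, var_residual = var_res),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("Broad-sense heritability H2 = %.3f (var_line = %.3g, var_residual = %.3g)\n",
              x$h2, x$var_line, x$var_residual))
  invisible(x)
}

#' @rdname broad_sense_heritability
#' @param x An `h2_estimate`.
#' @param ... Ignored.
#' @export
glance.h2_estimate <- function(x, ...) {
  tibble::tibble(h2 = x$h2, var_line = x$var_line,
                 var_residual = x$var_residual)
}

#' @rdname broad_sense_heritability
#' @export
tidy.h2_estimate <- function(x, ...) glance.h2_estimate(x)
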