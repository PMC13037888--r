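#' Sliding-window mean depth
#'
#' Tiles `[start, end)` of a depth profile with windows of `window` bp every
#' `step` bp and returns the mean per-base depth of each. A final partial
#' window of at most half the window size is merged into the previous
#' window; a profile shorter than one window becomes a single whole-profile
#' window with a warning.
#'
#' @param profile A [depth_profile()].
#' @param window Window size in bp (default 800).
#' @param step Step size in bp (default 400).
#' @return A tibble with columns `start`, `end` (0-based half-open, in the
#'   profile's coordinate system) and `depth` (mean reads/bp).
#' @export
window_depth <- function(profile, window = 800, step = 400) {
  stopifnot(inherits(profile, "depth_profile"), window >= step, step >= 1)
  len <- profile$end - profile$start
  if (len < window) {
    warning("profile shorter than one window; using a single whole-profile window")
    return(tibble::tibble(start = profile$start, end = profile$end,
                          depth = mean(profile$depth)))
  }
  starts <- seq(0, len - 1, by = step)
  ends <- pmin(starts + window, len)
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  m <- length(starts)
  if (m > 1 && (ends[m] - starts[m]) <= window / 2) {
    ends[m - 1] <- ends[m]
    starts <- starts[-m]; ends <- ends[-m]
    m <- m - 1
  }
  depth <- vapply(seq_len(m), function(i) {
    mean(profile$depth[(starts[i] + 1):ends[i]])
  }, numeric(1))
  tibble::tibble(start = profile$start + starts,
                 end = profile$start + ends,
                 depth = depth)
}

flank_mean_depth <- function(profile, breakpoints, flank, stat = mean) {
  bp1 <- breakpoints[[1]]; bp2 <- breakpoints[[2]]
  lo1 <- bp1 - flank; hi1 <- bp1
  lo2 <- bp2; hi2 <- bp2 + flank
  clip <- function(x) pmin(pmax(x, profile$start), profile$end)
  if (lo1 < profile$start || hi2 > profile$end) {
    warning("flank extends outside the depth profile; clipping to profile bounds")
  }
  idx <- function(lo, hi) {
    lo <- clip(lo); hi <- clip(hi)
    if (hi <= lo) integer(0)
    else (lo - profile$start + 1):(hi - profile$start)
  }
  pooled <- profile$depth[c(idx(lo1, hi1), idx(lo2, hi2))]
  if (!length(pooled) || stat(pooled) == 0) {
    stop("zero pooled flank depth: normalization impossible", call. = FALSE)
  }
  stat(pooled)
}

#' Normalize window depths to the breakpoint flanks
#'
#' Divides each window's mean depth by the pooled per-base mean depth of the
#' two `flank`-bp regions immediately upstream of the first breakpoint and
#' downstream of the second, giving copy-number ratios that are invariant to
#' overall sequencing depth. Flanks reaching outside the profile are clipped
#' with a warning.
#'
#' @param windows Output of [window_depth()].
#' @param profile The [depth_profile()] the windows were computed from.
#' @param breakpoints Numeric pair `(bp1, bp2)`, 0-based half-open, in the
#'   profile's coordinate system.
#' @param flank Flank length in bp (default 3000).
#' @param stat Summary applied to the pooled flank depths (`mean`, the
#'   default, or `median`).
#' @return `windows` with a `ratio` column appended.
#' @export
flank_normalize <- function(windows, profile, breakpoints, flank = 3000,
                            stat = mean) {
  fm <- flank_mean_depth(profile, breakpoints, flank, stat)
  dplyr::mutate(windows, ratio = .data$depth / fm)
}

#' Copy-number call from flank-normalized window depths
#'
#' Estimates the copy number of the region between two breakpoints as the
#' median flank-normalized depth ratio over the windows lying fully inside
#' `[bp1, bp2)`, rounded half-up to an integer (per haplotype; inbred lines
#' are homozygous).
#'
#' @inheritParams flank_normalize
#' @param window,step Sliding-window parameters passed to [window_depth()].
#' @return An object of class `cn_call`: a list with `region`,
#'   `window_ratios`, `median_ratio` and `cn`.
#' @export
estimate_cn <- function(profile, breakpoints, window = 800, step = 400,
                        flank = 3000, stat = mean) {
  bp1 <- breakpoints[[1]]; bp2 <- breakpoints[[2]]
  stopifnot(bp1 >= profile$start, bp2 <= profile$end, bp1 < bp2)
  w <- window_depth(profile, window = window, step = step)
  w <- flank_normalize(w, profile, breakpoints, flank = flank, stat = stat)
  inside <- w$start >= bp1 & w$end <= bp2
  if (!any(inside)) {
    stop("no window lies fully inside the breakpoints; try a smaller window",
         call. = FALSE)
  }
  ratios <- w$ratio[inside]
  med <- stats::median(ratios)
  structure(
    list(region = c(start = bp1, end = bp2), window_ratios = ratios,
         median_ratio = med, cn = as.integer(floor(med + 0.5))),
    class = "cn_call"
  )
}

#' @export
print.cn_call <- function(x, ...) {
  cat(sprintf("<cn_call> [%d, %d): median ratio %.3f over %d windows -> CN %d\n",
              x$region[["start"]], x$region[["end"]], x$median_ratio,
              length(x$window_ratios), x$cn))
  invisible(x)
}

#' @rdname estimate_cn
#' @param x A `cn_call`.
#' @param ... Ignored.
#' @export
glance.cn_call <- function(x, ...) {
  tibble::tibble(start = x$region[["start"]], end = x$region[["end"]],
                 n_windows = length(x$window_ratios),
                 median_ratio = x$median_ratio, cn = x$cn)
}

#' Candidate duplication spans from window depth ratios
#'
#' Flags maximal runs of at least `min_run` consecutive windows whose mean
#' depth exceeds `ratio_threshold` times the global median window depth —
#' a simple screen for duplicated spans to feed [estimate_cn()].
#'
#' @inheritParams window_depth
#' @param ratio_threshold Ratio to the global median above which a window is
#'   considered elevated (default 1.5).
#' @param min_run Minimum consecutive elevated windows (default 3).
#' @return A tibble with columns `start`, `end`, one row per candidate span
#'   (empty if none).
#' @export
detect_depth_changepoints <- function(profile, window = 800, step = 400,
                                      ratio_threshold = 1.5, min_run = 3) {
  w <- window_depth(profile, window = window, step = step)
  base <- stats::median(w$depth)
  if (base == 0) return(tibble::tibble(start = integer(), end = integer()))
  elevated <- w$depth / base > ratio_threshold
  r <- rle(elevated)
  stops <- cumsum(r$lengths)
  starts_idx <- stops - r$lengths + 1
  hit <- which(r$values & r$lengths >= min_run)
  tibble::tibble(
    start = w$start[starts_idx[hit]],
    end = w$end[stops[hit]]
  )
}

mask_n <- function(s, token) gsub("N", token, toupper(s), fixed = TRUE)

#' Classify a tandem-duplication breakpoint junction
#'
#' Locates the copy-1 terminal anchor (the `flank_probe` reference bases
#' ending at `dup_end`) and the copy-2 initial anchor (the `flank_probe`
#' bases starting at `dup_start`) in the junction-spanning sequence by exact,
#' case-insensitive match (`N` never matches). The relative placement of the
#' two anchors determines the call: an overlap of `k >= 1` bases is
#' microhomology (the motif is shared by both breakpoint ends of the
#' reference), intervening unmatched bases are a novel insertion, and exact
#' adjacency is a blunt junction.
#'
#' @param junction_seq Junction-spanning sequence (character string).
#' @param reference Reference sequence the duplication lives in.
#' @param dup_start,dup_end 1-based inclusive bounds of the duplicated
#'   segment.
#' @param flank_probe Anchor length in bp (default 50).
#' @return A [junction_call()].
#' @export
classify_junction <- function(junction_seq, reference, dup_start, dup_end,
                              flank_probe = 50L) {
  reference <- toupper(reference)
  read <- mask_n(junction_seq, "#")
  L <- nchar(reference)
  stopifnot(dup_end - flank_probe + 1 >= 1, dup_start + flank_probe - 1 <= L,
            dup_start < dup_end)
  anchor1 <- mask_n(subseq_chr(reference, dup_end - flank_probe + 1L, dup_end), "@")
  anchor2 <- mask_n(subseq_chr(reference, dup_start, dup_start + flank_probe - 1L), "@")

  i <- regexpr(anchor1, read, fixed = TRUE)[1]
  if (i < 0) stop("junction context does not match reference", call. = FALSE)
  hits <- gregexpr(anchor2, read, fixed = TRUE)[[1]]
  hits <- hits[hits >= i] # j == i when the homology spans the whole probe
  if (!length(hits) || hits[1] < 0) {
    stop("junction context does not match reference", call. = FALSE)
  }
  j <- hits[1]
  gap <- j - (i + flank_probe)
  if (gap > 0) {
    ins <- subseq_chr(junction_seq, i + flank_probe, j - 1L)
    junction_call("insertion", gap, ins)
  } else if (gap < 0) {
    k <- -gap
    motif <- subseq_chr(toupper(junction_seq), j, i + flank_probe - 1L)
    junction_call("microhomology", k, motif)
  } else {
    junction_call("blunt", 0L, "")
  }
}

#' @rdname classify_junction
#' @param x A `junction_call`.
#' @param ... Ignored.
#' @export
tidy.junction_call <- function(x, ...) {
  tibble::tibble(type = x$type, length = x$length, sequence = x$sequence)
}

#' Linkage between a structural variant and a SNP
#'
#' Squared Pearson correlation of the 0/1 carrier vector of a structural
#' variant with a SNP's 0/1 calls over the shared samples; pairs with a
#' missing value are dropped. `r^2 = 1` means the SV rides on a single SNP
#' haplotype (perfect LD).
#'
#' @param sv_carrier 0/1 carrier status per sample.
#' @param snp_calls 0/1 SNP calls per sample (same order).
#' @return Squared correlation, or `NA` if either vector is monomorphic
#'   after dropping missing pairs.
#' @export
sv_snp_ld <- function(sv_carrier, snp_calls) {
  stopifnot(length(sv_carrier) == length(snp_calls))
  ok <- !is.na(sv_carrier) & !is.na(snp_calls)
  x <- sv_carrier[ok]; y <- snp_calls[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(x, y)^2
}
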