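#' Read and write phenotype, BLUE, depth and association tables
#'
#' Plain TSV round-trip helpers for the pipeline's tabular interchange
#' formats. Depth tables are bedgraph-style (`chrom`, `start`, `end`,
#' `depth`; 0-based half-open, one row per base or run).
#'
#' @param table Tibble to write.
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_pheno_tsv <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_pheno_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    block = readr::col_character(),
                    accession = readr::col_character()
                  ))
}

#' @rdname table_io
#' @export
write_depth_tsv <- function(profile, path) {
  pos <- seq(profile$start, profile$end - 1L)
  readr::write_tsv(
    tibble::tibble(chrom = profile$chrom, start = pos, end = pos + 1L,
                   depth = profile$depth),
    path
  )
  invisible(path)
}

#' @rdname table_io
#' @param path File path.
#' @export
read_depth_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(d)))
  # expand run-length rows to per-base depth
  reps <- d$end - d$start
  depth <- rep(d$depth, reps)
  depth_profile(d$chrom[1], min(d$start), max(d$end), depth)
}

#' @rdname table_io
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names(sequences), path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(x, as.character, character(1))), names(x))
}

#' @rdname table_io
#' @param truth A [truth_record()].
#' @export
write_truth_yaml <- function(truth, path) {
  out <- list(
    seed = truth$seed,
    subpop_labels = as.list(truth$subpop_labels),
    causal_snps = if (nrow(truth$causal_snps)) {
      lapply(seq_len(nrow(truth$causal_snps)), function(i) {
        list(id = truth$causal_snps$id[i],
             effect = truth$causal_snps$effect[i])
      })
    } else list(),
    causal_td = truth$causal_td,
    true_h2 = truth$true_h2,
    junction_truth = if (!is.null(truth$junction_truth)) {
      list(type = truth$junction_truth$type,
           length = truth$junction_truth$length,
           sequence = truth$junction_truth$sequence)
    }
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_truth_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  truth_record(
    seed = raw$seed %||% NA_integer_,
    subpop_labels = unlist(raw$subpop_labels),
    causal_snps = if (length(raw$causal_snps)) {
      tibble::tibble(
        id = vapply(raw$causal_snps, function(x) x$id, character(1)),
        effect = vapply(raw$causal_snps, function(x) x$effect, numeric(1))
      )
    } else tibble::tibble(id = character(), effect = double()),
    causal_td = raw$causal_td,
    true_h2 = raw$true_h2 %||% NA_real_,
    junction_truth = if (!is.null(raw$junction_truth)) {
      junction_call(raw$junction_truth$type, raw$junction_truth$length,
                    raw$junction_truth$sequence %||% "")
    }
  )
}
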