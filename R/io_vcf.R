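#' Write a genotype matrix to VCF
#'
#' Writes biallelic records in VCF v4.2 with haploid `GT:DP:GQ` genotypes,
#' the on-disk representation used for inbred lines throughout the package.
#' Missing calls are written as `.` in the GT field (DP/GQ are still emitted
#' when present, so quality filtering can be replayed from the file).
#'
#' @param g A [geno_matrix()].
#' @param path Output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  v <- g$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tdgwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  gt <- t(g$calls) # variants x samples
  gt_chr <- matrix(as.character(gt), nrow = nrow(gt))
  gt_chr[is.na(gt)] <- "."
  fmt_field <- function(m, j) {
    if (is.null(m)) return(rep(".", nrow(gt)))
    col <- t(m)[, j]
    out <- as.character(col)
    out[is.na(col)] <- "."
    out
  }
  cells <- vapply(seq_along(g$samples), function(j) {
    paste(gt_chr[, j], fmt_field(g$dp, j), fmt_field(g$gq, j), sep = ":")
  }, character(nrow(v)))
  if (nrow(v) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT:DP:GQ",
    apply(cells, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Cheap structural pre-scan so malformed records can be reported with their
# line number (vcfR does not surface one).
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (!length(hdr_idx)) stop("no #CHROM header line in ", path, call. = FALSE)
  n_fields <- length(strsplit(lines[hdr_idx[1]], "\t", fixed = TRUE)[[1]])
  body <- seq(hdr_idx[1] + 1L, length.out = length(lines) - hdr_idx[1])
  for (ln in body) {
    if (!nzchar(lines[ln])) next
    k <- length(strsplit(lines[ln], "\t", fixed = TRUE)[[1]])
    if (k != n_fields) {
      stop(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                   ln, k, n_fields), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a VCF of inbred genotype calls
#'
#' Reads a VCF (via \pkg{vcfR}), keeps biallelic records only, and returns a
#' [geno_matrix()] with per-call DP and GQ. Haploid (`0`/`1`) and homozygous
#' diploid (`0/0`, `1/1`) GT codings are both accepted; heterozygous or
#' multi-allelic calls are set to missing. Malformed records abort with the
#' offending line number.
#'
#' @param path Path to a VCF file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE)
  vcf <- vcf[biallelic, ]
  fix <- fix[biallelic, , drop = FALSE]

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  allele <- gsub("[|/].*$", "", gt_raw) # first allele; inbred lines are homozygous
  het <- !is.na(gt_raw) & grepl("[|/]", gt_raw) &
    allele != gsub("^.*[|/]", "", gt_raw)
  calls <- suppressWarnings(matrix(as.integer(allele), nrow = nrow(gt_raw)))
  calls[het] <- NA_integer_
  calls[!is.na(calls) & !(calls %in% c(0L, 1L))] <- NA_integer_

  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)

  variants <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF,
    alt = fix$ALT
  )
  samples <- colnames(gt_raw)
  geno_matrix(
    calls = t(calls), variants = variants, samples = samples,
    dp = if (all(is.na(dp))) NULL else t(dp),
    gq = if (all(is.na(gq))) NULL else t(gq)
  )
}

#' Quality-filter genotype calls
#'
#' Applies the per-call completeness rule used before association mapping:
#' keep biallelic records only and set to missing any call whose read depth
#' is not strictly greater than `dp_min_exclusive` or whose genotype quality
#' is not strictly greater than `gq_min_exclusive` (defaults DP > 3, GQ > 20).
#'
#' @param g A [geno_matrix()] (as from [read_vcf()]) or a path to a VCF file.
#' @param dp_min_exclusive Calls need DP strictly greater than this.
#' @param gq_min_exclusive Calls need GQ strictly greater than this.
#' @return A [geno_matrix()] with failing calls set to missing.
#' @export
filter_genotypes <- function(g, dp_min_exclusive = 3, gq_min_exclusive = 20) {
  if (is.character(g)) g <- read_vcf(g)
  stopifnot(inherits(g, "geno_matrix"))
  calls <- g$calls
  fails <- function(q, cut) is.na(q) | q <= cut # missing quality fails the rule
  if (!is.null(g$dp)) calls[!is.na(calls) & fails(g$dp, dp_min_exclusive)] <- NA_integer_
  if (!is.null(g$gq)) calls[!is.na(calls) & fails(g$gq, gq_min_exclusive)] <- NA_integer_
  out <- g
  out$calls <- calls
  out
}
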