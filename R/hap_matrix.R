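#' Construct a haplotype / multilocus-genotype matrix
#'
#' The basic data container for a scan: one row per sequence (a haplotype in
#' phased mode, a diploid multilocus genotype in unphased mode), one column
#' per biallelic SNP. Allele codes are 0/1 for haplotypes and 0/1/2
#' (alt-allele dosage) for genotypes; missing calls are `NA`.
#'
#' @param alleles integer matrix, rows = sequences, columns = SNPs.
#' @param chrom character vector of per-SNP chromosome labels.
#' @param pos_bp integer vector of per-SNP physical positions (1-based bp),
#'   strictly increasing within each chromosome.
#' @param phased logical; `TRUE` for haplotype rows, `FALSE` for
#'   multilocus-genotype rows.
#' @param sample_ids optional row labels.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, chrom, pos_bp, phased = TRUE,
                       sample_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  nsnp <- ncol(alleles)
  chrom <- as.character(chrom)
  pos_bp <- as.numeric(pos_bp)
  if (length(chrom) != nsnp || length(pos_bp) != nsnp)
    stop("chrom and pos_bp must have one entry per SNP column")
  ok_codes <- if (phased) c(0L, 1L) else c(0L, 1L, 2L)
  vals <- alleles[!is.na(alleles)]
  if (length(vals) && !all(vals %in% ok_codes))
    stop("allele codes must be in {", paste(ok_codes, collapse = ","),
         "} or NA")
  if (phased && nrow(alleles) %% 2L != 0L)
    stop("phased mode expects an even number of haplotype rows (diploids)")
  for (ch in unique(chrom)) {
    pc <- pos_bp[chrom == ch]
    if (any(diff(pc) <= 0))
      stop("pos_bp must be strictly increasing within chromosome ", ch)
  }
  if (is.null(sample_ids))
    sample_ids <- paste0(if (phased) "hap" else "ind", seq_len(nrow(alleles)))
  structure(list(alleles = alleles, chrom = chrom, pos_bp = pos_bp,
                 phased = phased, sample_ids = as.character(sample_ids)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d %s x %d SNPs on %d chromosome(s) [%s]\n",
              nrow(x$alleles),
              if (x$phased) "haplotypes" else "multilocus genotypes",
              ncol(x$alleles), length(unique(x$chrom)),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)
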