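#' Expected-homozygosity summaries of a window spectrum
#'
#' Computed on the full (untruncated) ranked frequency spectrum of a
#' window. In haplotype mode returns H1 = sum f_j^2, the pooled-top-two
#' statistic H12 = (f1 + f2)^2 + sum_{j>=3} f_j^2 (sensitive to both hard
#' and soft sweeps) and the ratio H2/H1 = (H1 - f1^2)/H1 (large under soft
#' sweeps). In genotype mode the analogues for unphased multilocus
#' genotypes pool the top three classes: G1, G123 = (f1+f2+f3)^2 +
#' sum_{j>=4} f_j^2, and G2/G1.
#'
#' @param full_spectrum descending numeric frequencies summing to 1.
#' @param mode `"haplotype"` or `"genotype"`.
#' @return list with `h1`, `h12`, `h2h1` (haplotype mode) or `g1`, `g123`,
#'   `g2g1` (genotype mode).
#' @export
homozygosity_stats <- function(full_spectrum,
                               mode = c("haplotype", "genotype")) {
  mode <- match.arg(mode)
  f <- as.numeric(full_spectrum)
  if (abs(sum(f) - 1) > 1e-8) stop("spectrum must sum to 1")
  if (is.unsorted(rev(f))) stop("spectrum must be descending")
  h1 <- sum(f^2)
  npool <- if (mode == "haplotype") 2L else 3L
  top <- sum(f[seq_len(min(npool, length(f)))])
  rest <- if (length(f) > npool) sum(f[(npool + 1L):length(f)]^2) else 0
  pooled <- top^2 + rest
  ratio <- if (h1 > 0) (h1 - f[1]^2) / h1 else 0
  if (mode == "haplotype") list(h1 = h1, h12 = pooled, h2h1 = ratio)
  else list(g1 = h1, g123 = pooled, g2g1 = ratio)
}
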