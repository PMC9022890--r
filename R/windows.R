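#' Build SNP-delimited analysis windows
#'
#' Windows contain a fixed number of SNPs (`winsize`) and slide by a fixed
#' number of SNPs (`winstep`) along each chromosome. SNP-delimited windows
#' are preferred over fixed-bp windows because they are robust to local
#' variation in SNP density (recombination/mutation rate, mappability).
#' Trailing stretches shorter than `winsize` are not emitted, and windows
#' never span chromosomes.
#'
#' @param matrix a [hap_matrix()].
#' @param winsize window size in SNPs (>= 2).
#' @param winstep step between successive window starts, in SNPs (>= 1).
#' @return data.frame with columns `win_id` (genome-wide index), `chrom`,
#'   `first_snp`, `last_snp` (0-based inclusive column offsets into the
#'   chromosome's SNP list), `start_bp`, `end_bp` (positions of the first
#'   and last SNP), `chrom_windex` (1-based ordinal within the chromosome).
#' @export
build_windows <- function(matrix, winsize, winstep) {
  stopifnot(inherits(matrix, "hap_matrix"))
  winsize <- as.integer(winsize); winstep <- as.integer(winstep)
  if (is.na(winsize) || winsize < 2L) stop("winsize must be >= 2")
  if (is.na(winstep) || winstep < 1L) stop("winstep must be >= 1")
  chroms <- unique(matrix$chrom)  # keep file order
  sizes <- vapply(chroms, function(ch) sum(matrix$chrom == ch), integer(1))
  if (!any(sizes >= winsize))
    stop("no chromosome has >= winsize SNPs (winsize=", winsize,
         "; chromosome sizes: ",
         paste(sprintf("%s:%d", chroms, sizes), collapse = ", "), ")")
  out <- list()
  for (ch in chroms) {
    idx <- which(matrix$chrom == ch)   # global SNP columns, position order
    L <- length(idx)
    if (L < winsize) next
    starts <- seq.int(0L, L - winsize, by = winstep)
    out[[ch]] <- data.frame(
      chrom = ch,
      first_snp = starts,
      last_snp = starts + winsize - 1L,
      start_bp = matrix$pos_bp[idx[starts + 1L]],
      end_bp = matrix$pos_bp[idx[starts + winsize]],
      chrom_windex = seq_along(starts),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- cbind(win_id = seq_len(nrow(res)), res)
  res
}

#' Tally haplotype / genotype classes in one window
#'
#' Each retained row's allele string over the window's SNP columns is one
#' class. Rows with any missing call inside the window are dropped from that
#' window (so the per-window total can vary). Classes are returned sorted by
#' count (descending), ties broken by lexicographic class string, so the
#' output is deterministic.
#'
#' @param matrix a [hap_matrix()].
#' @param window one row of the data.frame from [build_windows()] (or any
#'   list with `chrom`, `first_snp`, `last_snp`).
#' @return named integer vector of class counts.
#' @export
window_class_counts <- function(matrix, window) {
  idx <- which(matrix$chrom == window$chrom)
  cols <- idx[(window$first_snp + 1L):(window$last_snp + 1L)]
  if (any(cols < 1L) || any(cols > ncol(matrix$alleles)))
    stop("window SNP offsets out of range")
  sub <- matrix$alleles[, cols, drop = FALSE]
  keep <- rowSums(is.na(sub)) == 0L
  if (!any(keep))
    stop("window unusable: all sequences have missing calls in [",
         window$chrom, ":", window$first_snp, "-", window$last_snp, "]")
  cls <- apply(sub[keep, , drop = FALSE], 1L, paste0, collapse = "")
  tab <- table(cls)
  counts <- as.integer(tab)
  nm <- names(tab)
  ord <- order(-counts, nm, method = "radix")
  setNames(counts[ord], nm[ord])
}

#' Truncate a class-count tally to its K largest classes
#'
#' Keeps the K most frequent classes (padding with zeros when fewer than K
#' are observed) and rescales the retained counts proportionally so they sum
#' to the total number of retained sequences `n_i`. Truncation therefore
#' redistributes the tail mass proportionally over the retained classes
#' rather than discarding it.
#'
#' @param raw_counts named or unnamed non-empty count vector (descending or
#'   not; it is sorted internally with the same tie rule as
#'   [window_class_counts()]).
#' @param K truncation level (>= 2).
#' @return list with `x` (length-K descending numeric counts summing to
#'   `n_i`), `n_i` (total retained sequences) and `n_distinct` (distinct
#'   classes observed before truncation).
#' @export
truncate_and_normalize <- function(raw_counts, K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("K must be >= 2")
  if (!length(raw_counts)) stop("raw_counts is empty")
  cnt <- as.numeric(raw_counts)
  nm <- names(raw_counts)
  ord <- if (is.null(nm)) order(-cnt) else order(-cnt, nm, method = "radix")
  cnt <- cnt[ord]
  n_i <- sum(cnt)
  n_distinct <- length(cnt)
  x <- cnt[seq_len(min(K, n_distinct))]
  if (length(x) < K) x <- c(x, rep(0, K - length(x)))
  retained <- sum(x)
  if (retained > 0 && retained != n_i) x <- x * (n_i / retained)
  list(x = x, n_i = n_i, n_distinct = n_distinct)
}

#' Genome-wide background spectrum
#'
#' The neutral expectation `p`: the unweighted mean over all genome-wide
#' windows of each window's normalized truncated spectrum, sorted descending
#' and renormalized. Entries are then floored at `1/(100K)` and the vector
#' renormalized once more, which guarantees `p_K > 0` so that the anchor
#' frequency `U = p_K` and the epsilon search interval are well defined.
#'
#' @param all_window_counts list of results from [truncate_and_normalize()]
#'   (every genome-wide window).
#' @param K truncation level.
#' @return numeric length-K descending probability vector.
#' @export
genome_background <- function(all_window_counts, K) {
  if (!length(all_window_counts)) stop("no windows to average")
  K <- as.integer(K)
  spectra <- vapply(all_window_counts,
                    function(w) w$x / w$n_i, numeric(K))
  p <- rowMeans(spectra)
  p <- sort(p, decreasing = TRUE)
  p <- p / sum(p)
  p <- pmax(p, 1 / (100 * K))
  p / sum(p)
}

# Per-window truncated counts + full (untruncated) spectrum for summaries.
# Internal driver used by hfs_scan().
window_spectra <- function(matrix, windows, K) {
  lapply(seq_len(nrow(windows)), function(i) {
    raw <- window_class_counts(matrix, windows[i, ])
    tn <- truncate_and_normalize(raw, K)
    tn$full_freq <- as.numeric(raw) / sum(raw)
    tn
  })
}
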