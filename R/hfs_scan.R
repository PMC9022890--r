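# Batch T statistic: one column of log-q-grid products per window.
lassi_T_all <- function(X, p, n_eps = 100L) {
  qg <- precompute_q_grid(p, n_eps)
  ll1 <- log(qg$Q) %*% t(X)            # n_combo x I
  ll0 <- drop(X %*% log(p))
  best <- apply(ll1, 2L, which.max)    # first max: smallest m, then eps
  list(T = 2 * (ll1[cbind(best, seq_len(ncol(ll1)))] - ll0),
       m_hat = qg$m[best], eps_hat = qg$eps[best])
}

#' Full haplotype-frequency-spectrum sweep scan
#'
#' The whole pipeline on a [hap_matrix()]: SNP-delimited windows,
#' per-window truncated spectra, the genome-wide background `p`, the
#' single-window statistic `T`, the spatial statistic `Lambda` with its
#' softness (`m_hat`) and footprint (`A_hat`) estimates, and
#' expected-homozygosity summaries (H12 and H2/H1, or G123 and G2/G1 for
#' unphased input).
#'
#' @param matrix a [hap_matrix()] (phased or unphased).
#' @param winsize,winstep window size and step in SNPs (defaults 201/100,
#'   the settings used for empirical genome scans; power-style analyses
#'   often use smaller windows, e.g. 51 or 101 SNPs with step 25).
#' @param K truncation level of the spectrum (default 20).
#' @param measure distance measure for window coordinates: `"bp"`
#'   (default), `"cm"` (requires `map`), or `"windex"`.
#' @param map optional genetic map from [read_genetic_map()].
#' @param targets window ids to fit (default: all windows).
#' @param n_eps epsilon grid resolution (default 100).
#' @return data.frame with one row per target window and the fixed
#'   16-column schema of [write_scan_table()].
#' @export
hfs_scan <- function(matrix, winsize = 201L, winstep = 100L, K = 20L,
                     measure = c("bp", "cm", "windex"), map = NULL,
                     targets = NULL, n_eps = 100L) {
  measure <- match.arg(measure)
  windows <- build_windows(matrix, winsize, winstep)
  spectra <- window_spectra(matrix, windows, K)
  p <- genome_background(spectra, K)
  z <- window_coordinates(windows, measure, map)
  X <- t(vapply(spectra, function(s) s$x, numeric(K)))
  if (is.null(targets)) targets <- windows$win_id
  fit <- salti_scan(X, z, windows$chrom, p, targets = targets,
                    n_eps = n_eps)
  tt <- lassi_T_all(X[targets, , drop = FALSE], p, n_eps)
  mode <- if (matrix$phased) "haplotype" else "genotype"
  summ <- lapply(spectra[targets],
                 function(s) homozygosity_stats(s$full_freq, mode))
  w <- windows[match(targets, windows$win_id), ]
  data.frame(
    chrom = w$chrom,
    win_id = w$win_id,
    start_bp = w$start_bp,
    end_bp = w$end_bp,
    mid = z[match(targets, windows$win_id)],
    n_snps = as.integer(winsize),
    n_obs = vapply(spectra[targets], function(s) s$n_i, numeric(1)),
    n_distinct = vapply(spectra[targets],
                        function(s) s$n_distinct, numeric(1)),
    h12_or_g123 = vapply(summ, function(s) s[[2]], numeric(1)),
    h2h1_or_g2g1 = vapply(summ, function(s) s[[3]], numeric(1)),
    T = tt$T,
    m_hat_T = tt$m_hat,
    lambda = fit$lambda,
    m_hat = fit$m_hat,
    log10_A_hat = log10(fit$A_hat),
    eps_hat = fit$eps_hat,
    stringsAsFactors = FALSE)
}
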