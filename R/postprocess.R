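#' Significance thresholds from neutral replicates
#'
#' Pools the per-window Lambda values of all neutral replicate scans and
#' returns the maximum together with the upper 0.1%, 1% and 5% quantiles.
#' Scanning real data against the pooled neutral maximum gives the most
#' conservative calls; the quantile thresholds support outlier-style
#' analyses when neutral simulations are unavailable or poorly calibrated.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param replicate_lambda_tables list of numeric vectors, or of
#'   data.frames carrying a `lambda` column (e.g. from
#'   [read_scan_table()]).
#' @return named list: `max`, `top0.1`, `top1`, `top5`.
#' @export
neutral_thresholds <- function(replicate_lambda_tables) {
  if (!is.list(replicate_lambda_tables) ||
      is.data.frame(replicate_lambda_tables))
    replicate_lambda_tables <- list(replicate_lambda_tables)
  pool <- unlist(lapply(replicate_lambda_tables, function(tab) {
    if (is.data.frame(tab)) tab$lambda else as.numeric(tab)
  }))
  pool <- pool[!is.na(pool)]
  if (!length(pool)) stop("no Lambda values to pool")
  qs <- quantile(pool, c(0.999, 0.99, 0.95), names = FALSE, type = 7)
  list(max = max(pool), top0.1 = qs[1], top1 = qs[2], top5 = qs[3])
}

#' Project simulated windows onto real-data windows
#'
#' Simulated genomes do not carry variants at the same sites as real data,
#' so their SNP-delimited windows do not align with the real-data windows.
#' For each real window this computes the mean Lambda of all simulated
#' windows overlapping it, weighted by bp overlap length; real windows
#' with no overlapping simulated window get `NA`.
#'
#' @param sim_rows data.frame with `chrom`, `start_bp`, `end_bp`, `lambda`.
#' @param real_windows data.frame with `chrom`, `start_bp`, `end_bp`.
#' @return numeric vector, one (possibly `NA`) Lambda per real window.
#' @export
align_sim_windows <- function(sim_rows, real_windows) {
  out <- rep(NA_real_, nrow(real_windows))
  for (ch in unique(real_windows$chrom)) {
    ri <- which(real_windows$chrom == ch)
    si <- which(sim_rows$chrom == ch)
    if (!length(si)) next
    rr <- IRanges::IRanges(real_windows$start_bp[ri],
                           real_windows$end_bp[ri])
    sr <- IRanges::IRanges(sim_rows$start_bp[si], sim_rows$end_bp[si])
    hits <- IRanges::findOverlaps(rr, sr)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(rr[qh], sr[sh]))
    lam <- sim_rows$lambda[si][sh]
    for (j in unique(qh)) {
      sel <- qh == j
      out[ri[j]] <- sum(ov[sel] * lam[sel]) / sum(ov[sel])
    }
  }
  out
}

#' Concatenate significant windows into candidate regions
#'
#' Windows with `lambda > threshold` are grouped into maximal runs of
#' consecutive window indices within a chromosome (overlapping windows in
#' a run merge naturally). Each region reports the softness and footprint
#' estimates of its best window.
#'
#' @param rows scan table (data.frame with `chrom`, `win_id`, `start_bp`,
#'   `end_bp`, `lambda`, `m_hat`, `log10_A_hat`), sorted by chromosome and
#'   window index.
#' @param threshold call windows with Lambda strictly above this value.
#' @return data.frame with one row per region: `chrom`, `start_bp`,
#'   `end_bp`, `m_hat`, `log10_A_hat`, `max_lambda`, `n_windows`, plus a
#'   list column `win_ids`.
#' @export
call_regions <- function(rows, threshold) {
  rows <- rows[order(rows$chrom, rows$win_id), ]
  sig <- rows[!is.na(rows$lambda) & rows$lambda > threshold, ]
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), m_hat = integer(0),
                      log10_A_hat = numeric(0), max_lambda = numeric(0),
                      n_windows = integer(0))
  if (!nrow(sig)) {
    empty$win_ids <- list()
    return(empty)
  }
  # new region whenever chromosome changes or window index jumps
  brk <- c(TRUE, diff(sig$win_id) != 1 |
             sig$chrom[-1] != sig$chrom[-nrow(sig)])
  grp <- cumsum(brk)
  regs <- lapply(split(sig, grp), function(g) {
    best <- which.max(g$lambda)  # ties: smaller window index
    data.frame(chrom = g$chrom[1],
               start_bp = min(g$start_bp),
               end_bp = max(g$end_bp),
               m_hat = g$m_hat[best],
               log10_A_hat = g$log10_A_hat[best],
               max_lambda = g$lambda[best],
               n_windows = nrow(g))
  })
  out <- do.call(rbind, regs)
  out$win_ids <- unname(lapply(split(sig$win_id, grp), as.integer))
  rownames(out) <- NULL
  out
}

#' Write a called-regions table
#' @param regions data.frame from [call_regions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_table <- function(regions, path) {
  cols <- c("chrom", "start_bp", "end_bp", "m_hat", "log10_A_hat",
            "max_lambda", "n_windows")
  fmt <- regions[, cols]
  for (cn in names(fmt))
    if (is.double(fmt[[cn]])) fmt[[cn]] <- sprintf("%.6g", fmt[[cn]])
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
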