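# Shared fixture builders: everything is generated in code at test time.

# random descending probability vector with the background floor applied,
# so it is a valid scan background (p_K > 0)
random_background <- function(K, floor_at = 1 / (100 * K)) {
  p <- sort(runif(K, 0.05, 1), decreasing = TRUE)
  p <- p / sum(p)
  p <- pmax(p, floor_at)
  p / sum(p)
}

# small deterministic haplotype matrix from explicit allele strings
hap_from_strings <- function(strings, chrom = NULL, pos = NULL,
                             phased = FALSE) {
  rows <- lapply(strsplit(strings, ""), function(s) {
    v <- suppressWarnings(as.integer(s))
    v  # "?" or any non-digit becomes NA
  })
  alle <- do.call(rbind, rows)
  nsnp <- ncol(alle)
  if (is.null(chrom)) chrom <- rep("1", nsnp)
  if (is.null(pos)) pos <- seq_len(nsnp) * 10
  hap_matrix(alle, chrom, pos, phased = phased)
}

# literal triple-nested-loop evaluation of the spatial grid search,
# independent of the scan implementation (q built from the piecewise
# distortion formula inline)
brute_force_fit <- function(X, z, p, i_star, A_values, eps_values) {
  K <- length(p)
  U <- p[K]
  build_q <- function(m, eps) {
    q <- p
    if (m < K) {
      k <- (m + 1):K
      q[k] <- if (m == K - 1) eps else
        U - ((k - m - 1) / (K - m - 1)) * (U - eps)
      f <- exp(-seq_len(m)); f <- f / sum(f)
      q[1:m] <- p[1:m] + f * sum(p[k] - q[k])
    }
    q
  }
  ll0 <- sum(X %*% log(p))
  best <- -Inf; arg <- NULL
  for (m in seq_len(K)) {
    for (A in A_values) {
      alpha <- exp(-A * abs(z - z[i_star]))
      for (eps in eps_values) {
        q <- build_q(m, eps)
        G <- outer(alpha, q) + outer(1 - alpha, p)
        ll <- sum(X * log(G))
        if (ll > best) {
          best <- ll
          arg <- list(m = m, A = A, eps = eps)
        }
      }
    }
  }
  list(lambda = 2 * (best - ll0), m_hat = arg$m, A_hat = arg$A,
       eps_hat = arg$eps)
}

# composite log-likelihood at one grid point, evaluated the oracle's way
oracle_ll <- function(X, z, p, i_star, m, A, eps) {
  K <- length(p)
  U <- p[K]
  q <- p
  if (m < K) {
    k <- (m + 1):K
    q[k] <- if (m == K - 1) eps else
      U - ((k - m - 1) / (K - m - 1)) * (U - eps)
    f <- exp(-seq_len(m)); f <- f / sum(f)
    q[1:m] <- p[1:m] + f * sum(p[k] - q[k])
  }
  alpha <- exp(-A * abs(z - z[i_star]))
  sum(X * log(outer(alpha, q) + outer(1 - alpha, p)))
}

# the scan's argmax must be the oracle's argmax, or tied with it at the
# oracle's own evaluation (distinct grid points can be equal to rounding)
expect_same_grid_optimum <- function(fit, bf, X, z, p, i_star) {
  expect_lte(abs(fit$lambda - bf$lambda), 1e-9)
  same <- fit$m_hat == bf$m_hat && fit$A_hat == bf$A_hat &&
    fit$eps_hat == bf$eps_hat
  if (same) {
    succeed()
  } else {
    ll_fit <- oracle_ll(X, z, p, i_star, fit$m_hat, fit$A_hat,
                        fit$eps_hat)
    ll_bf <- oracle_ll(X, z, p, i_star, bf$m_hat, bf$A_hat, bf$eps_hat)
    expect_lte(abs(ll_fit - ll_bf), 1e-9)
  }
}

# minimal VCF text for io tests
write_test_vcf <- function(lines_body, path, samples = c("s1", "s2", "s3")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines_body), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
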