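#' Mass weights for the sweeping haplotype classes
#'
#' When a sweep carries `m` haplotype classes to high frequency, the
#' probability mass freed from the non-sweeping tail is distributed over the
#' sweeping classes with exponentially decaying weights
#' `f_k = exp(-k) / sum_{j=1..m} exp(-j)`, so the top class receives the
#' largest share.
#'
#' @param m number of sweeping classes (>= 1).
#' @return numeric length-m descending weight vector summing to 1.
#' @export
sweep_mass_weights <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1")
  w <- exp(-seq_len(m))
  w / sum(w)
}

#' Sweep-distorted truncated spectrum q(m)
#'
#' Distorts the background spectrum `p` as expected under a sweep on `m`
#' haplotype classes. Non-sweeping classes `k = m+1..K` are assigned
#' frequencies that interpolate linearly from the anchor `U = p_K` down to
#' `epsilon`; the mass they lose relative to `p` is added to the sweeping
#' classes `k = 1..m` in proportion to [sweep_mass_weights()].
#'
#' Edge cases: with `m = K - 1` the single tail class gets `q_K = epsilon`;
#' with `m = K` there is no tail and `q = p` (the grid point is equivalent
#' to the null model).
#'
#' @param p background spectrum (descending, sums to 1, `p_K > 0`).
#' @param m number of sweeping classes, `1 <= m <= K`.
#' @param eps lowest non-sweeping frequency, `0 < eps <= U = p_K`.
#' @return numeric length-K descending probability vector.
#' @export
distorted_spectrum <- function(p, m, eps) {
  K <- length(p)
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > K) stop("m must be in 1..K")
  U <- p[K]
  if (U <= 0) stop("p_K must be positive (background floor not applied?)")
  if (eps <= 0 || eps > U + 1e-12) stop("eps must be in (0, U]")
  q <- p
  if (m < K) {
    k <- (m + 1L):K
    if (m == K - 1L) {
      q[K] <- eps
    } else {
      q[k] <- U - ((k - m - 1) / (K - m - 1)) * (U - eps)
    }
    freed <- sum(p[k] - q[k])
    f <- sweep_mass_weights(m)
    q[seq_len(m)] <- p[seq_len(m)] + f * freed
  }
  q
}

#' Epsilon search grid
#'
#' Equally spaced values on `[1/(100K), U]` with `U = p_K`. In the
#' degenerate case where flooring and renormalizing the background pushed
#' `p_K` slightly below `1/(100K)`, the lower end is clamped to `U` so the
#' interval stays non-empty.
#'
#' @param K truncation level.
#' @param U anchor frequency `p_K`.
#' @param n_eps number of grid points (default 100).
#' @return increasing numeric vector of length `n_eps`.
#' @export
epsilon_grid <- function(K, U, n_eps = 100L) {
  lo <- min(1 / (100 * K), U)
  if (n_eps < 1L) stop("n_eps must be >= 1")
  if (n_eps == 1L) return(U)
  seq(lo, U, length.out = n_eps)
}

# Precompute q(m, eps) over the full (m, eps) grid.
# Returns list(Q = matrix[n_combo x K], m = int vec, eps = num vec) with
# combos ordered m-major then eps (the tie-break order of the scan).
precompute_q_grid <- function(p, n_eps = 100L) {
  K <- length(p)
  eps <- epsilon_grid(K, p[K], n_eps)
  combos <- expand.grid(eps_i = seq_along(eps), m = seq_len(K))
  combos <- combos[order(combos$m, combos$eps_i), ]
  Q <- t(vapply(seq_len(nrow(combos)),
                function(i) distorted_spectrum(p, combos$m[i],
                                               eps[combos$eps_i[i]]),
                numeric(K)))
  list(Q = Q, m = as.integer(combos$m), eps = eps[combos$eps_i],
       eps_grid = eps)
}

#' Single-window likelihood ratio statistic T
#'
#' The non-spatial precursor of the spatial scan: for one window with
#' truncated counts `x`, `T = 2 [ max_{m,eps} sum_k x_k log q_k(m,eps)
#' - sum_k x_k log p_k ]`, maximized over the same `(m, eps)` grid the
#' spatial scan uses. Equivalent to the spatial statistic when the window
#' set is just the target window. `T` is reported unfloored.
#'
#' @param x_target numeric length-K truncated count vector (descending).
#' @param p background spectrum of the same length.
#' @param n_eps epsilon grid resolution (default 100).
#' @return list with `T`, `m_hat`, `eps_hat`.
#' @export
lassi_T <- function(x_target, p, n_eps = 100L) {
  K <- length(p)
  if (length(x_target) != K) stop("x_target and p must share K")
  if (any(p <= 0 & x_target > 0))
    stop("p has a zero entry with positive count")
  qg <- precompute_q_grid(p, n_eps)
  ll0 <- sum(x_target * log(p))
  ll1 <- drop(log(qg$Q) %*% x_target)
  best <- which.max(ll1)  # first index wins ties: smallest m, then eps
  list(T = 2 * (ll1[best] - ll0),
       m_hat = qg$m[best],
       eps_hat = qg$eps[best])
}
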