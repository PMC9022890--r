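test_that("decay weight is exponential in distance", {
  expect_equal(decay_alpha(2, 5, 5), 1)
  expect_equal(decay_alpha(log(2) / 7, 10, 3), 0.5)
  g <- build_A_grid(c(0, 1, 5))
  expect_equal(decay_alpha(g$A_min, 1, 0), 0.99999)
  expect_equal(decay_alpha(g$A_max, 1, 0), 0.00001)
  expect_error(decay_alpha(-1, 0, 1), "positive")
  # monotone in distance and in A
  d <- seq(0, 10, by = 0.5)
  expect_true(all(diff(decay_alpha(0.3, d, 0)) < 0))
  expect_true(all(diff(decay_alpha(c(0.1, 1, 5), 3, 0)) < 0))
})

test_that("A grid endpoints derive from d_min and scale as 1/d_min", {
  g <- build_A_grid(0:10)
  expect_length(g$A_values, 100)
  expect_equal(g$d_min, 1)
  expect_equal(g$A_min, -log(0.99999), tolerance = 1e-12)
  expect_equal(g$A_max, -log(0.00001), tolerance = 1e-12)
  expect_true(all(diff(g$A_values) > 0))
  g2 <- build_A_grid(seq(0, 10000, by = 1000))
  expect_equal(g2$A_values, g$A_values / 1000, tolerance = 1e-12)
  # per-chromosome coordinate lists; duplicate coordinates are an error
  g3 <- build_A_grid(list(c(0, 3, 6), c(100, 102)))
  expect_equal(g3$d_min, 2)
  expect_error(build_A_grid(c(0, 0, 5)), "d_min")
  expect_error(build_A_grid(list(5)), "windows")
})

test_that("mixture spectrum interpolates between background and sweep", {
  p <- c(0.6, 0.4); q <- c(0.9, 0.1)
  expect_equal(mixture_spectrum(p, q, 1), q)
  expect_equal(mixture_spectrum(p, q, 0), p)
  expect_equal(mixture_spectrum(p, q, 0.5), c(0.75, 0.25))
  set.seed(2)
  for (i in 1:50) {
    K <- sample(2:10, 1)
    pp <- random_background(K)
    qq <- distorted_spectrum(pp, sample(K, 1), pp[K] * runif(1))
    g <- mixture_spectrum(pp, qq, runif(1))
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_true(all(g >= 0))
  }
})

test_that("composite log-likelihoods evaluate the double sums", {
  expect_equal(loglik_null(c(3, 1), c(0.75, 0.25)),
               3 * log(0.75) + log(0.25))
  expect_equal(loglik_null(c(0, 0), c(0.75, 0.25)), 0)
  X <- rbind(c(3, 1), c(3, 1))
  expect_equal(loglik_null(X, c(0.75, 0.25)),
               2 * loglik_null(c(3, 1), c(0.75, 0.25)))
  # single-window alternative reduces to the distorted-spectrum likelihood
  p <- c(0.5, 0.3, 0.2)
  q <- distorted_spectrum(p, 1, 0.1)
  expect_equal(loglik_alt(c(5, 2, 1), z = 0, p, q, A = 1, i_star = 1),
               sum(c(5, 2, 1) * log(q)))
  # flanking windows shrink toward the null as A grows
  z <- c(0, 1, 2)
  X3 <- rbind(c(5, 2, 1), c(4, 3, 1), c(3, 3, 2))
  llA <- loglik_alt(X3, z, p, q, A = -log(1e-5), i_star = 1)
  target_term <- sum(X3[1, ] * log(q))
  null_rest <- loglik_null(X3[2:3, ], p)
  expect_equal(llA, target_term + null_rest, tolerance = 1e-3)
})

test_that("scan equals the literal triple-loop grid search on random instances", {
  set.seed(19)
  for (rep in 1:6) {
    K <- sample(3:5, 1); I <- sample(8:25, 1)
    p <- random_background(K)
    z <- sort(sample.int(500, I))
    X <- t(sapply(seq_len(I), function(i)
      sort(rmultinom(1, 40, p)[, 1], decreasing = TRUE)))
    i_star <- sample.int(I, 1)
    ag <- build_A_grid(z)
    eg <- epsilon_grid(K, p[K], 30)
    fit <- salti_scan(X, z, p = p, targets = i_star, A_grid = ag,
                      n_eps = 30)
    bf <- brute_force_fit(X, z, p, i_star, ag$A_values, eg)
    expect_same_grid_optimum(fit, bf, X, z, p, i_star)
  }
})

test_that("expected counts at a grid point are recovered exactly", {
  set.seed(23)
  K <- 6; I <- 51
  p <- random_background(K)
  z <- seq_len(I)
  ag <- build_A_grid(z)
  eg <- epsilon_grid(K, p[K])
  m0 <- 2L; A0 <- ag$A_values[50]; eps0 <- eg[25]
  q0 <- distorted_spectrum(p, m0, eps0)
  i_star <- 26L
  alpha <- decay_alpha(A0, z, z[i_star])
  X <- 200 * (outer(alpha, q0) + outer(1 - alpha, p))
  fit <- salti_scan(X, z, p = p, targets = i_star, A_grid = ag)
  expect_equal(fit$m_hat, m0)
  expect_equal(fit$A_hat, A0)
  expect_equal(fit$eps_hat, eps0)
  expect_gt(fit$lambda, 0)
})

test_that("restricting the window set to the target reduces to the T statistic", {
  set.seed(31)
  ag <- build_A_grid(c(0, 1))
  for (rep in 1:20) {
    K <- sample(3:8, 1)
    p <- random_background(K)
    x <- sort(rmultinom(1, 60, p)[, 1], decreasing = TRUE)
    fit <- salti_scan(rbind(x), z = 0, p = p, targets = 1, A_grid = ag)
    tt <- lassi_T(x, p)
    expect_lt(abs(fit$lambda - tt$T), 1e-12)
    expect_equal(fit$m_hat, tt$m_hat)
    expect_equal(fit$eps_hat, tt$eps_hat)
  }
})

test_that("Lambda is invariant to coordinate shifts and chromosome relabeling", {
  set.seed(37)
  K <- 5; I <- 30
  p <- random_background(K)
  z <- sort(sample.int(300, I))
  X <- t(sapply(seq_len(I), function(i)
    sort(rmultinom(1, 50, p)[, 1], decreasing = TRUE)))
  f1 <- salti_scan(X, z, p = p, targets = c(5, 15))
  f2 <- salti_scan(X, z + 1e5, p = p, targets = c(5, 15))
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-9)
  expect_equal(f1$m_hat, f2$m_hat)
  f3 <- salti_scan(X, z, chrom = rep("chrZ", I), p = p, targets = c(5, 15))
  expect_equal(f1$lambda, f3$lambda)
})

test_that("windows on other chromosomes cancel from the ratio", {
  set.seed(41)
  K <- 4
  p <- random_background(K)
  z1 <- seq_len(12)
  X1 <- t(sapply(z1, function(i)
    sort(rmultinom(1, 30, p)[, 1], decreasing = TRUE)))
  # append a second chromosome: Lambda at targets on chr1 must not change
  z2 <- seq_len(8)
  X2 <- t(sapply(z2, function(i)
    sort(rmultinom(1, 30, p)[, 1], decreasing = TRUE)))
  ag <- build_A_grid(list(z1, z2))
  f_alone <- salti_scan(X1, z1, p = p, targets = 4, A_grid = ag)
  f_joint <- salti_scan(rbind(X1, X2), c(z1, z2),
                        chrom = rep(c("1", "2"), c(12, 8)), p = p,
                        targets = 4, A_grid = ag)
  expect_equal(f_alone$lambda, f_joint$lambda)
  expect_equal(f_alone$m_hat, f_joint$m_hat)
})
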