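test_that("window offsets follow the winsize/winstep rule and never span chromosomes", {
  set.seed(1)
  mk <- function(nsnp_per_chrom) {
    chrom <- rep(names(nsnp_per_chrom), nsnp_per_chrom)
    pos <- unlist(lapply(nsnp_per_chrom, function(n) seq_len(n) * 7))
    alle <- matrix(sample(0:1, 4 * sum(nsnp_per_chrom), replace = TRUE), 4)
    hap_matrix(alle, chrom, pos)
  }
  # 500 SNPs, winsize 201, winstep 100: offsets 0,100,200 only
  w <- build_windows(mk(c(chr1 = 500)), 201, 100)
  expect_equal(w$first_snp, c(0, 100, 200))
  expect_equal(w$last_snp, c(200, 300, 400))
  expect_equal(nrow(w), 3L)
  # exact fit: one window
  w1 <- build_windows(mk(c(chr1 = 201)), 201, 100)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$first_snp, w1$last_snp), c(0, 200))
  # two chromosomes of 251 SNPs: 9 windows each, none spanning
  w2 <- build_windows(mk(c(chr1 = 251, chr2 = 251)), 51, 25)
  expect_equal(nrow(w2), 18L)
  expect_equal(as.integer(table(w2$chrom)), c(9L, 9L))
  expect_equal(w2$first_snp[w2$chrom == "chr2"], seq(0, 200, 25))
  # no chromosome long enough
  expect_error(build_windows(mk(c(chr1 = 50)), 51, 25), "winsize")
})

test_that("class counting drops rows with missing calls and orders deterministically", {
  hm <- hap_from_strings(c("00", "00", "01", "11"))
  w <- list(chrom = "1", first_snp = 0L, last_snp = 1L)
  cnt <- window_class_counts(hm, w)
  expect_equal(cnt, c("00" = 2L, "01" = 1L, "11" = 1L))
  # identical rows collapse to one class
  hm2 <- hap_from_strings(rep("111", 4))
  cnt2 <- window_class_counts(hm2, list(chrom = "1", first_snp = 0L,
                                        last_snp = 2L))
  expect_equal(unname(cnt2), 4L)
  # missing call excludes the whole row from this window
  hm3 <- hap_from_strings(c("00", "0?", "11"))
  cnt3 <- window_class_counts(hm3, w)
  expect_equal(cnt3, c("00" = 1L, "11" = 1L))
  # all rows missing -> unusable window
  hm4 <- hap_from_strings(c("0?", "?1"))
  expect_error(window_class_counts(hm4, w), "unusable")
  # equal counts tie-break: lexicographic class string
  hm5 <- hap_from_strings(c("11", "00", "01", "01", "11", "00"))
  expect_equal(names(window_class_counts(hm5, w)), c("00", "01", "11"))
})

test_that("truncation keeps the K largest classes and rescales to n_i", {
  tn <- truncate_and_normalize(c(10, 5, 3, 2, 2, 1), 4)
  expect_equal(tn$x, c(11.5, 5.75, 3.45, 2.3))
  expect_equal(sum(tn$x), tn$n_i)
  expect_equal(tn$n_distinct, 6L)
  # fewer classes than K: zero padding, no rescale
  tn2 <- truncate_and_normalize(c(7, 3), 4)
  expect_equal(tn2$x, c(7, 3, 0, 0))
  expect_equal(tn2$n_i, 10)
  # ties at the truncation boundary are resolved by the class-string rule
  tn3 <- truncate_and_normalize(c(a = 4, b = 4, c = 4), 2)
  expect_equal(tn3$x, c(6, 6))
  expect_equal(tn3$n_i, 12)
  expect_error(truncate_and_normalize(c(3, 2), 1), "K")
})

test_that("no mass is lost when K covers all distinct classes", {
  set.seed(42)
  for (rep in 1:20) {
    cnt <- sample(1:30, sample(2:8, 1), replace = TRUE)
    names(cnt) <- sprintf("c%02d", seq_along(cnt))
    tn <- truncate_and_normalize(cnt, length(cnt) + sample(0:3, 1))
    expect_equal(sum(tn$x), sum(cnt))
    expect_equal(sort(tn$x[tn$x > 0], decreasing = TRUE),
                 sort(as.numeric(cnt), decreasing = TRUE))
  }
})

test_that("background spectrum averages windows, then floors and renormalizes", {
  w1 <- list(x = c(8, 2), n_i = 10)
  w2 <- list(x = c(6, 4), n_i = 10)
  expect_equal(genome_background(list(w1, w2), 2), c(0.7, 0.3))
  # single window: identity (fixed point of the mean)
  expect_equal(genome_background(list(w1), 2), c(0.8, 0.2))
  # all-monomorphic genome: floor at 1/(100K) then renormalize
  mono <- list(x = c(10, 0, 0, 0, 0), n_i = 10)
  p <- genome_background(list(mono, mono), 5)
  expect_equal(p, c(1, rep(0.002, 4)) / 1.008)
  expect_gt(p[5], 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(genome_background(list(), 5), "window")
})

test_that("window spectra are descending and sum to their totals", {
  set.seed(7)
  alle <- matrix(sample(0:1, 40 * 60, replace = TRUE), 40)
  hm <- hap_matrix(alle, rep("1", 60), seq_len(60) * 50)
  w <- build_windows(hm, 10, 5)
  sp <- hapsweep:::window_spectra(hm, w, 8)
  for (s in sp) {
    expect_equal(sum(s$x), s$n_i, tolerance = 1e-12)
    expect_true(all(diff(s$x) <= 1e-12))
    expect_true(all(s$x >= 0))
  }
  p <- genome_background(sp, 8)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(diff(p) <= 1e-12))
})
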