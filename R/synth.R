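#' Specify a generative sweep model for synthetic data
#'
#' Bundles the parameters of the sampling model used by the synthetic-data
#' generators: a background spectrum `p`, true sweep parameters
#' `(m0, A0, eps0)`, a focal window, and the window layout. Window `i` at
#' distance `d_i` from the focal window samples sequences from the mixture
#' `g_i = alpha_i q(m0, eps0) + (1 - alpha_i) p` with
#' `alpha_i = exp(-A0 d_i)` — exactly the spectra the scan models.
#'
#' The defaults emulate the conditions used throughout validation: a
#' Zipf-like neutral background over K = 10 classes, I = 201 windows at
#' unit spacing (window-number distance), the focal window in the middle,
#' n = 200 sequences per window, and a moderate footprint (`A0` about
#' 0.047 per window, i.e. the sweep's influence fades within ~50 windows).
#' `A0` and `eps0` default to values on the scan's own search grids so
#' that parameter recovery is an exact-grid question.
#'
#' @param K truncation level.
#' @param p background spectrum (length K, descending, sums to 1).
#' @param m0 true number of sweeping classes.
#' @param A0 true decay rate (default: the grid value nearest 0.05 for the
#'   implied unit-spacing grid).
#' @param eps0 true tail frequency (default: mid grid).
#' @param i_star focal window index.
#' @param I number of windows.
#' @param spacing inter-window distance (coordinates are
#'   `z_i = (i-1) * spacing`).
#' @param n sequences sampled per window.
#' @return list of class `generative_model`.
#' @export
generative_model <- function(K = 10L, p = NULL, m0 = 1L, A0 = NULL,
                             eps0 = NULL, i_star = NULL, I = 201L,
                             spacing = 1, n = 200L) {
  K <- as.integer(K)
  if (is.null(p)) {
    p <- (1 / seq_len(K)) / sum(1 / seq_len(K))
    p <- pmax(p, 1 / (100 * K))
    p <- p / sum(p)
  }
  if (length(p) != K || any(diff(p) > 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a descending length-K probability vector")
  if (is.null(i_star)) i_star <- (I + 1L) %/% 2L
  z <- (seq_len(I) - 1) * spacing
  grid <- build_A_grid(z)
  if (is.null(A0)) grid_A0 <- grid$A_values[which.min(abs(
    grid$A_values - 0.05 / spacing))] else grid_A0 <- A0
  eg <- epsilon_grid(K, p[K])
  if (is.null(eps0)) eps0 <- eg[length(eg) %/% 2L]
  m0 <- as.integer(m0)
  if (m0 < 1L || m0 > K) stop("m0 must be in 1..K")
  if (grid_A0 <= 0) stop("A0 must be positive")
  if (eps0 <= 0 || eps0 > p[K] + 1e-12) stop("eps0 must be in (0, p_K]")
  structure(list(K = K, p = p, m0 = m0, A0 = grid_A0, eps0 = eps0,
                 i_star = as.integer(i_star), I = as.integer(I),
                 spacing = spacing, n = as.integer(n), z = z,
                 A_grid = grid),
            class = "generative_model")
}

# Per-window RNG streams: seeds drawn from the root seed's own stream
# with replacement, so the first I values are a prefix of the first I'
# values for I' > I (extending the window set never perturbs earlier
# windows) while distinct root seeds give unrelated window streams.
window_seeds <- function(seed, I) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max, I, replace = TRUE)
}

# Expected mixture spectrum at every window of a generative model:
# I x K matrix of g_i(m0, A0, eps0).
model_mixture_matrix <- function(model) {
  q <- distorted_spectrum(model$p, model$m0, model$eps0)
  alpha <- decay_alpha(model$A0, model$z, model$z[model$i_star])
  outer(alpha, q) + outer(1 - alpha, model$p)
}

#' Sample per-window truncated counts from a generative model
#'
#' Draws, for every window `i`, a multinomial sample of `n` sequences from
#' the mixture spectrum `g_i(m0, A0, eps0)` and sorts the counts
#' descending (the scan only ever sees ranked spectra). Each window uses
#' its own RNG stream derived from the root seed, so extending the window
#' set does not perturb earlier windows.
#'
#' @param model a [generative_model()].
#' @param seed root RNG seed.
#' @return list with `X` (I x K descending count matrix), `z`
#'   (coordinates) and `G` (the I x K matrix of sampling probabilities).
#' @export
sample_model_counts <- function(model, seed = 1L) {
  stopifnot(inherits(model, "generative_model"))
  G <- model_mixture_matrix(model)
  X <- matrix(0, model$I, model$K)
  ws <- window_seeds(seed, model$I)
  for (i in seq_len(model$I)) {
    set.seed(ws[i])
    X[i, ] <- sort(rmultinom(1L, model$n, G[i, ])[, 1], decreasing = TRUE)
  }
  list(X = X, z = model$z, G = G)
}

#' Generate a mosaic haplotype matrix with sweep-like spatial structure
#'
#' An end-to-end fixture generator: each window region gets `K` prototype
#' haplotypes (i.i.d. equal-probability alleles, redrawn until every
#' site's minor allele count among the prototypes is at least
#' `maf_floor`), and every sampled sequence independently picks a
#' prototype per window with the mixture probabilities
#' `g_i(m0, A0, eps0)`. Windows are non-overlapping and SNP positions are
#' laid out with fixed spacing, so scanning the result with
#' `winsize = winstep = n_snps_per_window` reconstructs the intended
#' windows and their expected spectra. Within-window linkage structure
#' (recombination-driven LD decay) is intentionally not modeled: the
#' generator targets the sufficient statistics of the likelihood, the
#' per-window ranked spectra.
#'
#' @param model a [generative_model()]. In phased output the model's `n`
#'   is the number of haplotypes and must be even.
#' @param n_snps_per_window SNPs per window region (>= 2).
#' @param maf_floor minimum prototype minor-allele count per site
#'   (default 2; must be `<= K/2`).
#' @param seed root RNG seed.
#' @param bp_spacing distance between adjacent SNPs in bp (default 100).
#' @return list with `matrix` (a phased [hap_matrix()]), `labels`
#'   (I x n true class assignments) and `windows_truth` (the intended
#'   window layout).
#' @export
generate_mosaic_haplotypes <- function(model, n_snps_per_window = 21L,
                                       maf_floor = 2L, seed = 1L,
                                       bp_spacing = 100L) {
  stopifnot(inherits(model, "generative_model"))
  L <- as.integer(n_snps_per_window)
  if (L < 2L) stop("n_snps_per_window must be >= 2")
  if (maf_floor > model$K / 2)
    stop("maf_floor must be <= K/2 so prototype sites can satisfy it")
  if (model$n %% 2L != 0L) stop("model$n must be even for phased output")
  G <- model_mixture_matrix(model)
  nsnp <- model$I * L
  alle <- matrix(NA_integer_, model$n, nsnp)
  labels <- matrix(NA_integer_, model$I, model$n)
  ws <- window_seeds(seed, model$I)
  for (i in seq_len(model$I)) {
    set.seed(ws[i])
    proto <- matrix(0L, model$K, L)
    for (s in seq_len(L)) {
      repeat {
        col <- rbinom(model$K, 1L, 0.5)
        mac <- min(sum(col), model$K - sum(col))
        if (mac >= maf_floor) break
      }
      proto[, s] <- col
    }
    pick <- sample.int(model$K, model$n, replace = TRUE, prob = G[i, ])
    labels[i, ] <- pick
    cols <- ((i - 1L) * L + 1L):(i * L)
    alle[, cols] <- proto[pick, , drop = FALSE]
  }
  pos <- seq_len(nsnp) * as.integer(bp_spacing)
  hm <- hap_matrix(alle, rep("1", nsnp), pos, phased = TRUE)
  truth <- data.frame(win = seq_len(model$I),
                      first_snp = (seq_len(model$I) - 1L) * L,
                      last_snp = seq_len(model$I) * L - 1L)
  list(matrix = hm, labels = labels, windows_truth = truth)
}

#' Write a phased haplotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only records; consecutive haplotype row
#' pairs form one diploid sample with a phased genotype. Used to hand
#' synthetic fixtures to the file-based pipeline.
#'
#' @param matrix a phased [hap_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hap_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "hap_matrix"), matrix$phased)
  n_hap <- nrow(matrix$alleles)
  n_ind <- n_hap %/% 2L
  ids <- sprintf("ind%03d", seq_len(n_ind))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapsweep-synthetic-mosaic",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  a1 <- matrix$alleles[seq(1L, n_hap, by = 2L), , drop = FALSE]
  a2 <- matrix$alleles[seq(2L, n_hap, by = 2L), , drop = FALSE]
  nsnp <- ncol(matrix$alleles)
  gt <- matrix(paste0(a1, "|", a2), n_ind, nsnp)
  gt[is.na(a1) | is.na(a2)] <- ".|."
  body <- vapply(seq_len(nsnp), function(s) {
    paste(c(matrix$chrom[s], format(matrix$pos_bp[s], scientific = FALSE),
            ".", "A", "T", ".", "PASS", ".", "GT", gt[, s]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
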