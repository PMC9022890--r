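---
title: "Detecting selective sweeps from spatial distortions of the haplotype frequency spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps from spatial distortions of the haplotype frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsweep)
```

## The model

A selective sweep drives one or a few haplotype backgrounds to high
frequency, distorting the haplotype frequency spectrum (HFS) of windows
near the selected site. `hapsweep` detects and characterizes sweeps by
modeling this distortion and, crucially, its decay with distance from the
sweep.

The data are the `K`-truncated ranked spectra of sliding SNP-delimited
windows. For window $i$ with truncated counts
$x_i = (x_{i1}, \dots, x_{iK})$ summing to $n_i$ sequences, the neutral
expectation is the genome-wide background spectrum
$p = (p_1, \dots, p_K)$, the average of all window spectra. A sweep on
$m$ haplotype classes distorts $p$ into $q(m)$: the non-sweeping classes
$k = m+1, \dots, K$ are squeezed onto a linear ramp from the anchor
$U = p_K$ down to a free parameter $\varepsilon$, and the mass they lose
is given to the sweeping classes with exponentially decaying weights
$f_k = e^{-k} / \sum_{j=1}^{m} e^{-j}$:

$$
q_k(m) =
\begin{cases}
p_k + f_k \sum_{j=m+1}^{K} (p_j - q_j(m)) & k \le m,\\[4pt]
U - \dfrac{k-m-1}{K-m-1}\,(U - \varepsilon) & k > m.
\end{cases}
$$

The spatial signature enters through a mixture: a window at coordinate
$z_i$, when the sweep is tested at target window $i^\star$, has expected
spectrum

$$
g_i(m, A) = \alpha_i(A)\, q(m) + [1 - \alpha_i(A)]\, p,
\qquad \alpha_i(A) = e^{-A |z_i - z_{i^\star}|},
$$

so the target window is fully distorted ($\alpha = 1$), distant windows
are neutral ($\alpha \to 0$), and the decay rate $A$ is the inverse scale
of the sweep's footprint. Because $\alpha_i \to 0$ far from the target,
neutrality is nested within the sweep model.

Treating windows as independent (a composite likelihood; recombination is
ignored), the test statistic at each target window is

$$
\Lambda = 2\left[\max_{m, \varepsilon, A} \sum_{i} \sum_{k}
x_{ik} \log g_{ik}(m, A) - \sum_i \sum_k x_{ik} \log p_k\right],
$$

with the argmax reported as the softness estimate $\hat m$ (1 = hard
sweep, >1 = soft sweep), the footprint estimate $\hat A$ (reported as
$\log_{10} \hat A$; smaller means wider), and $\hat\varepsilon$. The
statistic is not floored at zero and is not standardized; negative values
are meaningful "no support" outputs. The single-window statistic $T$
(the same maximization with the window set reduced to the target) is
reported alongside, as are the expected-homozygosity summaries H12 and
H2/H1 (phased input) or G123 and G2/G1 (unphased multilocus genotypes),
computed on the full untruncated window spectrum.

## Parameters that matter

* `winsize`, `winstep` (SNPs; defaults 201/100). Windows are SNP-delimited
  rather than physical-length, which buffers variation in SNP density.
  The defaults suit dense genome-wide scans; power-style analyses of
  simulated regions often use 51 or 101 SNP windows stepped every 25 SNPs,
  which resolve older or weaker sweeps better.
* `K` (default 20): spectrum truncation level. Detection power is fairly
  insensitive to `K`; the resolution of $\hat m$ is not (larger `K`
  permits a wider range of softness estimates).
* Distance measure for $z_i$: physical bp midpoints (default),
  centiMorgans via a genetic map (linear interpolation between anchors,
  clamped beyond the map ends), or window number. `A` is "per unit" of
  whichever measure is active.
* The search grids. $m \in \{1, \dots, K\}$ (the $m = K$ point leaves
  $q = p$ and is the null model, retained so the grid nests neutrality);
  $\varepsilon$: 100 equally spaced points on $[1/(100K), U]$; $A$: 100
  log-spaced values from $A_{\min} = -\ln(0.99999)/d_{\min}$ to
  $A_{\max} = -\ln(0.00001)/d_{\min}$, where $d_{\min}$ is the smallest
  inter-window distance genome-wide. At $A_{\min}$ the sweep's influence
  barely decays between the closest windows; at $A_{\max}$ it is
  essentially gone.

## Numerical choices

* Background floor: after averaging and renormalizing, `p` entries are
  floored at $1/(100K)$ and renormalized, so $U = p_K > 0$ and all log
  terms are finite. If renormalization leaves $p_K$ marginally below
  $1/(100K)$ (only possible in near-degenerate genomes), the
  $\varepsilon$ interval is clamped to remain valid.
* Truncation: the top-`K` class counts are rescaled proportionally to sum
  to $n_i$, so truncated tail mass is redistributed rather than dropped.
  Sequences with a missing call anywhere in a window are excluded from
  that window only.
* Tie-breaks, all deterministic: equal class counts are ordered
  lexicographically by allele string; grid ties resolve to the smallest
  $m$, then smallest $A$, then smallest $\varepsilon$.
* Edge cases of the distortion: $m = K-1$ collapses the one-class tail to
  $q_K = \varepsilon$; $m = K$ yields $q = p$ exactly.
* The grid evaluation in C++ pools windows at identical distances and
  skips mixture terms whose weight cannot move the mixture by half an ulp
  of $p_k$ ($\alpha < \min_k p_k \cdot 10^{-18} / \max |q - p|$). Both are
  exact to floating-point rounding — they are reorderings, not
  approximations — and the test suite verifies agreement with a literal
  triple-loop evaluation to $10^{-9}$. When targets share a small set of
  distinct window distances (regular lattices), per-$(A, d, m,
  \varepsilon)$ log terms are computed once and reused across targets;
  irregular coordinates fall back to per-target evaluation.
* Windows on chromosomes other than the target's contribute identical
  terms to the null and alternative composite likelihoods and cancel in
  $\Lambda$; both sums are therefore restricted to the target's
  chromosome.

## Empirical post-processing

Genome scans are calibrated empirically. `neutral_thresholds()` pools
per-window $\Lambda$ from neutral replicate scans and returns the
maximum and the upper 0.1%/1%/5% quantiles (linear interpolation between
order statistics — stated explicitly because "top 1%" alone does not fix
the convention; under it, pooling duplicated replicates shifts quantiles
by at most one order-statistic gap). When neutral windows do not align
with the real-data windows (simulated genomes carry variants at different
sites), `align_sim_windows()` projects them by bp-overlap-weighted means.
`call_regions()` concatenates consecutive significant windows
(consecutive in window index, so overlapping windows merge naturally)
into candidate regions; each region reports the $\hat m$ and
$\log_{10} \hat A$ of its maximum-$\Lambda$ window — the per-window
estimates are the primitive quantities, and the best window is the least
noisy summary of a region.

## The synthetic-data generator

`generative_model()` + `sample_model_counts()` sample window counts
directly from the mixture $g_i(m_0, A_0, \varepsilon_0)$ — the model's
own sufficient statistics — and rank them, exactly as a scan would see
them. Defaults represent the validation conditions used throughout:
$I = 201$ unit-spaced windows, $K = 10$, a Zipf-like background
($p_k \propto 1/k$, a reasonable caricature of a neutral ranked HFS),
$n = 200$ sequences per window, the focal window in the middle, and
$(A_0, \varepsilon_0)$ on the search grids ($A_0 \approx 0.047$ per
window, a footprint of roughly 20 windows; $\varepsilon_0$ mid-grid).
`generate_mosaic_haplotypes()` goes one level deeper: it materializes
per-window prototype haplotypes and lets each sample pick one per window
with probabilities $g_i$, yielding VCF-level fixtures whose expected
window spectra equal $g_i$ by construction.

Per-window RNG streams are derived from the root seed's own stream, so
extending the window set never perturbs earlier windows while distinct
root seeds give independent genomes.

What the generators deliberately omit: recombination-driven LD decay
within windows, mutation on sweeping backgrounds, and demography. They
target the likelihood's sufficient statistics, so passing tests show the
estimator works when the model holds — they say nothing about robustness
to bottlenecks, background selection, or rate variation, which require
external forward or coalescent simulators (fixtures are handed over as
VCF for exactly that purpose).

## Validation results and known limitations

The test suite verifies, among others: exact agreement of the grid scan
with an exhaustive triple-loop oracle (50 random instances, $10^{-9}$);
reduction of $\Lambda$ to $T$ on single-window sets ($10^{-12}$);
closed-form worked examples of $q(m)$, $f$, the $A$-grid endpoints, H12
and G123; exact recovery of $(m_0, A_0, \varepsilon_0)$ from expected
counts at a grid point; and mass conservation across 1000 random
distortions. Under the default study conditions, softness recovery is
exact in the mode for hard sweeps and $m_0 = 2$, and footprint recovery
has median $|\log_{10}\hat A - \log_{10}A_0|$ well under 0.5 throughout;
null genomes give a 99th-percentile $\Lambda$ a few percent of the median
hard-sweep $\Lambda$.

Known limitations:

* **Ranking bias in softness estimates.** Because window spectra are
  ranked before fitting, the order statistics of many near-equal
  low-frequency classes inflate the mid-rank counts relative to their
  class expectations at moderate $n$. At $n = 200$, $K = 10$ this shifts
  the modal $\hat m$ for a true $m_0 = 4$ to 5 (the mode sits on
  $\{m_0, m_0 + 1\}$; the estimator is consistent and recovers $m_0$
  exactly at large $n$ or from expected counts). Softness estimates for
  soft sweeps should be read as approximate — reliable for separating
  hard from soft, cruder for the exact class count, echoing the
  behaviour of non-spatial HFS likelihood estimators.
* $\hat A$ confounds sweep strength and age; it measures the footprint,
  not either quantity separately.
* Composite likelihood ignores recombination-rate variation, so strong
  signals in low-recombination regions deserve extra scrutiny, and
  $\Lambda$ has no asymptotic null distribution — calibrate empirically.
* Grid-search estimates are only as fine as the grids; $\hat A$
  resolution is about 0.06 decades with the default 100-point grid.

## Problem sizes used in checks

Validation uses desk-scale problem sizes chosen to exercise every code
path: oracle comparisons on $I \le 25$, $K = 5$ instances; recovery and
calibration at the generator defaults ($I = 201$, $K = 10$, $n = 200$,
100 replicates per setting; 500 null target fits in the test suite, 200
in the acceptance script); end-to-end VCF scans on mosaic genomes of
9-41 windows. Genome-scale scans use the same code paths (the scan is
$O(\text{targets} \times K \cdot n_\varepsilon \cdot n_A \cdot I)$ per
chromosome, with the shared-table fast path when window spacing is
regular).
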