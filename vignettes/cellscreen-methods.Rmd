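---
title: "Screening cell lines for genomic abnormalities: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cell lines for genomic abnormalities: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellscreen)
```

## The screening problem

Cultured cell lines — induced pluripotent stem cell lines in particular —
accumulate genomic aberrations during reprogramming and passaging: point
mutations, copy-number variants (CNVs), whole-chromosome aneuploidies, and
occasionally cross-sample contamination. SNP genotyping arrays are a cheap,
high-throughput way to screen for the larger events. Each array marker
yields two derived signals:

* **BAF** (B allele frequency): the fraction of fluorescent signal from the
  alternate allele. In a diploid region BAF clusters near 0, 0.5 and 1 for
  the RR, RA and AA genotypes.
* **LRR** (Log R Ratio): the log-scaled ratio of observed to expected total
  intensity, near 0 for diploid copy number, elevated for gains and lowered
  for losses.

`cellscreen` implements two complementary detectors on these signals plus a
simulation benchmark and an evaluator:

1. **Whole-chromosome screen** (`call_polysomy()`): aneuploidy and
   contamination from the shape of each chromosome's BAF distribution.
2. **Sub-chromosomal CNV caller** (`call_cnv()`, `call_cnv_pair()`):
   a four-state hidden Markov model over BAF and LRR, with a 16-state
   paired mode that reports *differences* between a cell line and the
   material it derives from, ignoring variation shared by both.

## Whole-chromosome screen

### Peak geometry

If a fraction $f$ of cells carries a third copy of a chromosome, the
heterozygous BAF cluster splits into two peaks at

$$\beta = \frac{1}{2+f} \quad\text{and}\quad \beta = \frac{1+f}{2+f},$$

i.e. at a shift $\delta = f/(2(2+f))$ from 0.5; inverting,
$f = 4\delta/(1-2\delta)$. Contamination by a second individual at mixture
fraction $f$ instead produces a symmetric pattern on *every* chromosome: a
central peak (both genomes heterozygous), side peaks at $(1 \mp f)/2$
(host heterozygous, contaminant homozygous), and outer peaks at $f/2$ and
$1 - f/2$ (host homozygous, contaminant heterozygous), so $f = 2\delta$
for the side-peak shift $\delta$. Because relabelling which genome is
"host" swaps $f$ and $1-f$ without changing the peak set, the mixture
fraction is identifiable only up to that complement; we report the minor
component, the convention used when quoting contamination levels.

### Fitting

Per chromosome the BAF values are histogrammed (100 bins over $[0,1]$),
smoothed with a 5-bin moving average, and local minima delimit the peaks.
The dominant homozygous RR peak is excluded from the model (the AA peak
optionally included) and the central region is rescaled to a maximum of 1.
The defaults — bin width and smoothing window — were chosen so that a peak
of standard deviation 0.03, the low end of realistic BAF noise, still spans
at least six bins.

Three constrained Gaussian-sum models are fitted with Levenberg–Marquardt
least squares (`minpack.lm`):

* **CN2**: one peak fixed at 0.5;
* **CN3**: two peaks at $0.5 \pm \delta$ with equal magnitudes;
* **CN4/contamination**: a central peak, side peaks at $0.5 \pm \delta$
  with independent magnitudes, and outer peaks at $\delta$ and
  $1 - \delta$ (which is where the host-homozygous/contaminant-
  heterozygous clusters sit when $f = 2\delta$). Without the outer peaks
  a strong contamination (say 40%) drives the side-peak fit toward a
  merged compromise between the two flanking cluster pairs.

All peaks in a fit share one width, bounded in $[0.01, 0.15]$; side-peak
models are restarted from $\delta_0 \in \{0.05, 0.1, 0.17, 0.25\}$ and the
best converged local optimum kept (lowest mean absolute deviation, ties to
the smaller shift). The goodness of fit is the mean absolute deviation
between model and scaled histogram over the fitted bins.

### Model selection and gates

More peaks never fit worse, so aberrant models must *earn* their extra
structure:

* an aberrant fit is accepted only if its deviation is below 30% of the
  single-peak (CN2) deviation (`fit_gate`);
* the implied cell fraction must be at least 20% (`min_fraction`) — below
  that the side peaks are not cleanly separable from a single noisy peak
  (values slightly above $f = 1$, which noise can produce for a full
  trisomy, are clamped to 1);
* the contamination model must additionally show a central peak of
  magnitude at least 0.1 in scaled units (`min_central_peak`): a
  contamination pattern always has a central heterozygous cluster, and
  without this requirement the model can mimic a clean trisomy using its
  outer peaks alone;
* between the two aberrant models the same nesting logic is applied
  again: the richer contamination model displaces the trisomy model only
  when its deviation is below `fit_gate` times the trisomy deviation;
* if no aberrant model is accepted and the CN2 fit itself deviates by
  more than 0.3 in scaled units (or failed to converge), the chromosome
  is reported `FAIL` rather than forced into a state.

At the sample level, contamination is distinguished from trisomy by its
genome-wide footprint: when more than half the chromosomes carry a
converged side-peak signature at mutually consistent shifts (spread
< 0.05), the verdict is contamination and the per-chromosome calls are
relabelled. The signature deliberately ignores the per-chromosome
`min_fraction` gate: a sub-threshold signature on one chromosome means
little, but the same shift recurring on most chromosomes is exactly the
pattern a contaminating genome produces, and pooling across chromosomes
supplies the evidence each chromosome alone lacks. In practice the screen
resolves trisomies and contaminations down to roughly 20–25% of cells;
below that the central clusters merge.

## The CNV hidden Markov model

### States and emissions

Four copy-number states: CN0 (homozygous loss), CN1 (single-copy loss),
CN2 (diploid), CN3 (single-copy gain). Higher gains are not modelled
separately — for integrity screening CN3 vs CN4 makes no practical
difference, and a separate CN4 state is hard to keep stably separated from
CN3.

BAF peaks are truncated Gaussians
$G(\beta, \beta_0) = c_{\beta_0} e^{-(\beta-\beta_0)^2/d^2}$ normalized to
unit area on $[0,1]$ (the normalizer of a boundary peak at 0 or 1 is twice
that of an interior peak), with scale $d = 0.04$ by default. Genotype
priors $f_{RR}, f_{RA}, f_{AA}$ come from the site allele frequency under
Hardy–Weinberg proportions. Per state:

* CN1: peaks at 0 and 1 weighted $f_{RR} + \tfrac12 f_{RA}$ and
  $f_{AA} + \tfrac12 f_{RA}$ (heterozygous sites lose one allele);
* CN2: peaks at 0, 0.5, 1 weighted by the genotype priors;
* CN3: homozygous peaks plus heterozygous peaks at $\beta_0$ and
  $1 - \beta_0$, each weighted $\tfrac12 f_{RA}$, with $\beta_0 = 1/3$
  when every cell carries the gain;
* CN0: no BAF model (density 0).

LRR is Gaussian around state means $\mu = (-0.45, 0, 0.3)$ for CN1..CN3
with scale $\Lambda = 0.2$, normalized to 1 at the mode.

The combined per-site emission blends the two signals with weights
$b$ (BAF) and $l$ (LRR) and an error floor:

$$P(\beta,\lambda \mid s) = P_{err} +
  \bigl(1 - b\,(1 - P(\beta \mid s))\bigr)
  \bigl(1 - l\,(1 - P(\lambda \mid s))\bigr).$$

The defaults $b = 1$, $l = 0.2$ encode that LRR is far less reproducible
across array runs than BAF; $l$ caps the LRR contribution at a factor
$1/(1-l)$ per marker, so a wild LRR value can never overwhelm the BAF
evidence. The BAF density enters this formula rescaled by its maximum
attainable interior-peak mode $1/(d\sqrt{\pi})$, which makes the weighted
factor an order-1 quantity as the blending formula presumes; the relative
ranking of states at a site is unchanged by the rescale. $P_{err}$
defaults to $10^{-4}$. CN0 carries neither a BAF nor an LRR model and
emits the error floor alone; in single-sample decoding it is effectively
unreachable, which is intended — with genotyping-array data a homozygous
loss manifests as a run of missing calls, which single-sample mode skips.
Paired mode keeps such sites, giving the no-call emission 0.5 for CN0 and
$0.5/3$ for each other state. A missing LRR simply drops the LRR factor at
that site.

### Transitions, distance, and decoding

The transition matrix has all off-diagonal entries equal to a per-base
probability $p$ ($10^{-9}$ by default) and is powered by the marker
distance in base pairs: between markers $i$ and $j$ the chain applies
$T^{j-i}$. Powers up to 10,000 are precomputed; longer gaps use
exponentiation by squaring, capped at 10 Mb beyond which the powered
matrix is numerically indistinguishable from its limit at this $p$.
Initial probabilities prefer the diploid state: $P(s{=}2) = 0.5$ and
$0.5/3$ for each other state. Decoding is by the Viterbi
algorithm in log space; per-site posteriors come from the scaled
forward–backward algorithm, and a segment's quality is the mean posterior
of its assigned state over its markers (also reported Phred-scaled,
capped at 99). Viterbi ties are broken toward CN2, then toward the lower
state index, making output deterministic.

### Paired calling

For a query/control pair the state space is the product (16 states) and
the emission is the product of the single-sample emissions. The joint
transition favours concordant moves through a shared-state prior
$\sigma \in [0,1]$: transitions that land the two samples in the same
state get a $\sigma$-weighted boost, transitions into discordant pairs are
damped by $1-\sigma$, and rows are renormalized over destination pairs.
At $\sigma = 0$ the joint matrix is exactly the Kronecker product of the
single-sample matrices and paired decoding factorizes into two independent
single-sample runs; at $\sigma = 1$ no discordant segment can be created.
(The source description of the concordant-diagonal case is internally
inconsistent as printed — taken literally it would not depend on $\sigma$
— and the row normalization is written as a sum over sources, which cannot
give a stochastic matrix; we use the $\sigma$-interpolated form above,
which reproduces both limiting behaviours, and normalize over
destinations.) An inherited CNV present in both samples comes out as a
concordant non-diploid state pair, not as a difference: this is the
mechanism by which paired mode ignores normal population variation in the
control.

### Re-estimating the gain shift

When only a fraction $f$ of cells carries a gain, the heterozygous
clusters sit at $1/(2+f)$, closer to 0.5 than the default $\beta_0 = 1/3$,
and the gain emission can drop below the diploid one — missing the region
entirely. `optimize_beta0()` iterates: run forward–backward, then update

$$\beta_0' = \frac{\sum_i (0.5 - |0.5 - \beta_i|)\, P_i(s{=}3)}
                  {\sum_i P_i(s{=}3)}$$

over heterozygous sites $i$ (by symmetry only the lower cluster needs
considering). Iteration stops on convergence ($|\beta_0' - \beta_0| <
10^{-4}$), after 20 rounds, or when $0.5 - \beta_0'$ falls below
$z_{0.95}\, d/\sqrt{2}$ — the point where a Gaussian BAF cluster can no
longer keep 95% of its mass below 0.5, i.e. where the two heterozygous
clusters stop being separable at the current noise level; the last
acceptable value is kept. If the total gain posterior mass over
heterozygous sites is below $10^{-3}$ marker-equivalents there is nothing
to estimate and the default is kept.

## The simulator

`simulate_experiment()` emulates one genotyping-array chromosome under
the conditions the benchmark is defined for:

* **Markers**: exponential inter-marker gaps with median 2 kb (the median
  spacing of a 0.5M-marker array) over a 40 Mb chromosome, ~13,900
  markers per experiment.
* **Genotypes**: per-site alternate-allele frequencies from a U-shaped
  Beta$(a,a)$ site-frequency distribution with $a$ set so the expected
  Hardy–Weinberg heterozygosity is 15%, the value typical of such arrays;
  genotypes drawn per site from Hardy–Weinberg proportions.
* **Noise**: per-experiment BAF noise sd uniform in $[0.03, 0.08]$ and
  LRR noise sd uniform in $[0.13, 0.26]$ — the ranges observed in real
  array data; BAF clipped to $[0,1]$.
* **Aberrations**: a zero-truncated Poisson number per experiment with
  mean rate 2 (≈ 2.3 realized), equally likely CN1 or CN3, placed
  uniformly without overlap. Lengths follow a *two-piece* log-normal
  hitting the published quantiles — 1st percentile 18 kb, median 1.7 Mb,
  99th percentile 4 Mb — exactly by construction: a single log-normal
  cannot satisfy all three (the lower tail spans a factor 94 below the
  median, the upper only 2.35 above), so the two half-widths are fitted
  separately. Deletions lose one allele clonally; gains shift the
  heterozygous clusters to $1/(2+f)$ and $(1+f)/(2+f)$, with LRR means
  $-0.45$ and $0.3$ scaled by the aberrant-cell fraction (the benchmark
  uses $f = 1$).

What the simulator does *not* emulate: GC waves and other systematic LRR
biases, batch effects, array-specific probe selection, genotype-calling
errors correlated with copy number, and linkage structure in the allele
frequencies. Passing benchmarks on this generator therefore demonstrates
correctness of the model and decoder under the stated noise model, not
robustness to the systematic artefacts of real arrays; LRR in particular
reproduces poorly between replicate array runs, which is precisely why
$l = 0.2$ down-weights it.

`simulate_polysomy_baf()` generates whole-chromosome BAF for the
aneuploidy screen: trisomy at fraction $f$ (clusters at $1/(2+f)$,
$(1+f)/(2+f)$) or contamination as a true two-genome mixture (both
genotypes drawn at the same site frequency, dosage mixed at $f$), which
reproduces the central/side/outer peak structure described above.

## Evaluation conventions

A truth region counts as detected if any called segment of the matching
*direction* overlaps it by at least one base pair (losses match CN0/CN1
calls, gains match CN3); a non-diploid call is a false positive if it
overlaps no truth region of matching direction; CN2 calls are ignored.
The FDR denominator is the number of called non-diploid segments
(call-level, not base-pair-level). One call overlapping two truth regions
detects both; two calls overlapping one truth region count once as a
detection and both contribute to the added-length statistic. Boundary
accuracy is summarized per detected region as missed length (truth not
covered) and added length (call outside truth).

## Problem sizes and runtime

The package-level benchmark (`run_cnv_benchmark()`) uses 500 experiments
of one 40 Mb chromosome each (≈ 1,150 aberrations), which a single core
decodes in a few minutes with the vectorized R implementation; the
distribution self-tests use $10^4$–$10^5$ draws. These sizes give binomial
95% confidence of roughly ±1–2 percentage points on the headline rates.

## Known limitations

* **Deletion sensitivity is transition-limited at default settings.** A
  deletion changes each heterozygous marker's BAF from 0.5 to 0/1, but
  the emission likelihood ratio between CN1 and CN2 at such a marker is
  bounded by $(f_{RR} + \tfrac12 f_{RA})/f_{RR}$ (plus the capped LRR
  factor $1/(1-l)$) — order one per marker — while entering and leaving a
  segment costs $2|\log(\text{gap} \cdot p)| \approx 26$ nats at 2 kb
  spacing and $p = 10^{-9}$. Reliable deletion calls therefore need
  dozens of markers, not a handful; gains are far easier because a
  heterozygous BAF near 1/3 is essentially impossible under the diploid
  model (likelihood ratio $\sim 10^3$–$10^5$ per marker). Raising $p$
  trades this against false positives.
* Gain false positives arise in high-noise experiments (BAF sd
  approaching 0.08, twice the emission scale $d$), where stray
  heterozygous values near 1/3 mimic the gain clusters; they are the
  dominant false-positive class by construction of the signal.
* The screen cannot separate contamination fractions $f$ from $1-f$
  (mixture label symmetry) and reports the minor component.
* Sex chromosomes are not special-cased; exclude them via region filters
  when screening male samples.
* Absolute copy number beyond the CN3 pattern is out of scope.
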