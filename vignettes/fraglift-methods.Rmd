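---
title: "fraglift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fraglift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraglift)
```

`fraglift` estimates the tumour-derived fraction of cell-free DNA in a
plasma sample from fragmentomic features of its length distribution.
This vignette records the model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and the limits of what the
synthetic experiments demonstrate.

## Fragment profiles

The unit of input is a per-sample histogram of absolute fragment lengths
in bp. Counts are normalized over the full recorded support (the
simulator uses 50–400 bp) rather than only over the analysis windows,
because the feature windows are subsets (81–141 and 81–336 bp) of a
distribution whose overall mass matters for the proportions. A
pseudocount (default 0.5, the usual continuity correction) is added to
every bin before normalization so that the log-profile is finite even in
sparsely covered length ranges; with zero pseudocount and an empty bin
the transform is refused rather than silently patched. Proportions are
exactly invariant to uniform scaling of counts when the pseudocount is
zero and approximately so otherwise.

When histograms are derived from alignments, we count absolute template
lengths of first-in-pair, properly paired, primary, non-duplicate
records with mapping quality ≥ 30. These filters are our choice:
libraries differ, and fragment-size profiles are known to be sensitive
to extraction and processing protocols, so the filter set is exposed as
arguments and recorded rather than hidden.

## Fourier features (81–141 bp)

On the log scale the sub-nucleosomal range is dominated by a smooth
decaying trend with a superimposed ~10 bp oscillation from the helical
pitch of nucleosome-bound DNA. We remove the trend by ordinary least
squares on \((1, j, j^2)\) over \(j = 81..141\) and transform the 61
residuals \(\hat\varepsilon_n\), \(n = j - 81\):

\[ F_k \;=\; \sum_{n=0}^{60} \hat\varepsilon_n\, e^{-2\pi i k n / 61},
   \qquad k = 0..60. \]

The convention is deliberate: negative exponent, no \(1/N\) factor —
`stats::fft` computes exactly this sum. Residuals of an intercept fit
are centred, so \(F_0 = 0\); conjugate symmetry gives
\(|F_{61-k}| = |F_k|\), so the magnitudes \(|F_1|..|F_{30}|\) (features
`F1`..`F30`) are the complete non-redundant set. A 10 bp period over a
61-point window corresponds to \(k \approx 6\). Magnitudes, not real or
imaginary parts, are used: they are invariant to the phase of the
oscillation relative to the window boundary.

## Wavelet features (81–336 bp)

Transient shape changes — the short-fragment bulge, the inter-peak
valley — are captured by a discrete wavelet transform of the log profile
over the 256 lengths 81..336 bp. We use the Daubechies filter of length
10 because its support matches the 10 bp oscillation period, and a
*decimated, orthonormal, periodized* pyramid transform with 6
decomposition levels by default:

* decimated (rather than maximal-overlap), because it yields the compact
  `W{scale}_{location}` naming with \(2^{-j}\) coefficients per scale
  and makes the total coefficient count equal the window length (256 =
  128 + 64 + 32 + 16 + 8 + 4 detail coefficients plus 4 approximation
  coefficients, labelled scale 7);
* orthonormal, so coefficient energy equals input energy — an invariant
  the tests check to 1e-9 — and no information is double-counted;
* periodized, because it is the only boundary rule that keeps a decimated
  transform exactly orthogonal on a finite window. The wrap-around
  couples the two window ends; for the default depth this touches the
  first few locations of each scale, which the polynomial-annihilation
  test explicitly excludes.

The transform input is the log profile itself, not the detrended
residuals: scaling-function coefficients absorb smooth trends, and the
five vanishing moments of the length-10 filter annihilate polynomial
trends up to degree four within each filter support.

The depth (6) and boundary rule are configuration, not claims: they are
recorded in the returned object, and feature names are part of the
serialized-model contract. Feature order is fixed — `F1`..`F30`, then
wavelet coefficients by scale and location — so feature matrices align
across samples and releases.

## Tumour-content labels

For samples with deep panel sequencing, tumour content is estimated from
somatic SNVs restricted to copy-number-neutral loci (diploid, no loss of
heterozygosity; mutations with unknown status are conservatively
excluded). Assuming heterozygous mutations, a clonal mutation's variant
allele frequency is half the tumour fraction, so:

1. cluster VAFs with a Dirichlet-process binomial mixture —
   concentration \(\alpha = 1\), \(\mathrm{Beta}(1,1)\) base measure on
   each cluster's VAF, collapsed Gibbs sampling (default 2000 sweeps,
   seeded, initialized from a single cluster);
2. take the cluster with the largest posterior-mean VAF — unless all its
   members are non-annotated variants and another cluster exists, in
   which case the second-largest is used (a guard against artefacts
   masquerading as high-VAF clusters);
3. double that VAF and clip into \((\varepsilon, 1-\varepsilon)\),
   \(\varepsilon = 10^{-3}\), because the downstream beta regression
   needs an open-interval response.

The point clustering is the sampled state with the highest joint
posterior score, which on small mutation sets (the relevant regime —
panels yield a handful of usable SNVs) agrees with exhaustive
enumeration of all partitions in ≥ 18/20 seeded instances in our tests.
Posterior-mean cluster VAFs (rather than modes or raw frequencies) are
used for the doubling; with conjugate Beta–binomial clusters the mean is
the natural point estimate and is defined even for single-member
clusters. Samples without usable panel SNVs take surrogate labels from
an external copy-number-based estimator, read from file and never
computed here; zero-valued surrogate labels carry no signal for a model
of \((0,1)\) responses and are dropped with a count.

## Boosted beta regression

Tumour content is modelled with the mean/precision beta density
\(f(y;\mu,\phi)\), \(\operatorname{logit}\mu = \eta\) linear in
standardized features. Because samples are fewer than features, the
model is fitted by component-wise gradient boosting: at each iteration
the negative gradient of the summed negative log-likelihood with respect
to \(\eta\) is computed, each feature is least-squares-fitted to it
singly, and the best-fitting feature's coefficient advances by
\(\nu = 0.1\) times its fitted slope. Single-feature linear base
learners are the canonical choice that produces linear coefficient
paths. The precision \(\phi\) is a scalar nuisance refreshed each
iteration by one-dimensional likelihood maximization on
\(\log\phi \in [-4, 8]\) (golden-section search, tolerance 1e-6); the
offset is fixed at \(\operatorname{logit}(\bar y)\). Numerical guards:
responses exactly 0 or 1 are rejected (squeezing is the label module's
job), constant feature columns are dropped with a warning, and the
logistic mean is clamped to \([10^{-10}, 1-10^{-10}]\) inside the
likelihood so saturated linear predictors cannot produce non-finite
terms.

The stopping iteration `mstop` is the regularization parameter. It is
tuned by bootstrap cross-validation: 25 resamples of size \(n\) with
replacement, one boosting path fitted per resample, out-of-bag mean
negative log-likelihood evaluated at every candidate `mstop`, averaged
across folds; ties in the mean risk go to the smallest `mstop`
(parsimony). Resamples with an empty out-of-bag set are redrawn. With
one feature and enough iterations the boosted coefficient converges to
the direct maximum-likelihood estimate (checked against `optim` to
1e-3), so boosting here is regularization, not approximation.

Models serialize to JSON with 17 significant digits — the smallest
count that round-trips IEEE doubles — so restored models reproduce
predictions bit-for-bit.

## Stability selection

Features are shortlisted by complementary-pairs stability selection: for
each of \(B = 50\) pairs, the samples are split at random into two
disjoint halves of size \(\lfloor n/2\rfloor\) (odd \(n\): one random
sample sits out per pair), boosting runs on each half until \(q\)
distinct features have entered (capped at \(10q\) iterations so runs
terminate even when fewer than \(q\) features can enter), and selection
frequencies are tallied over the \(2B\) runs. Of the three control
parameters — \(q\), the frequency cutoff \(\pi_{thr}\), and the
per-family expected false positives (PFER) — exactly two are set and the
third is derived from the Meinshausen–Bühlmann bound
\(\mathrm{PFER} \le q^2 / ((2\pi_{thr} - 1)\,p)\). The default budget is
PFER = 1 with cutoff 0.75, giving \(q = \lfloor\sqrt{0.5\,p}\rfloor\)
(11 for the default 286 features). Only the MB bound is implemented: it
is simple and conservative; the tighter unimodal bound would require
assumptions we cannot verify here, and we preferred a guarantee we can
state exactly. Under a global null the mean number of selected features
over 20 seeded replicates stays within the budget in our tests.

One practical caveat the small-study tests surfaced: coarse wavelet
features are strongly correlated, and with very small half-samples they
split votes, so no single feature may reach a 0.75 cutoff even when the
signal is obvious. For small cohorts, deriving the cutoff from
\((q, \mathrm{PFER})\) instead (e.g. \(q = 3\), PFER = 1) keeps the
error budget while lowering the threshold honestly.

## Evaluation

Dilution-series concordance is summarized by regressing predicted tumour
content on the known spike-in concentration. With an intercept,
\(R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}\) about the mean; through the
origin we report the *uncentred* convention
\(R^2_0 = 1 - \mathrm{RSS}_0/\sum y^2\), the convention R's `lm` uses
for intercept-free fits. The two conventions are not comparable and no
ordering between them is asserted — pathological configurations can
reverse it — so both are reported and each is tested against
normal-equations oracles.

## What the synthetic data does and does not show

The generator plants the structure the method assumes: two-component
truncated-normal nucleosomal mixtures (healthy modes 166/332 bp, sds
9/20, weights 0.88/0.12; tumour modes 145/300 bp, sds 12/25, weights
0.90/0.10), cosine oscillations of period 10 bp on the short side of
each peak (amplitude 0.05 healthy, 0.15 tumour), a uniform density floor
of \(10^{-6}\) before renormalization, multinomial sampling of
\(5\times10^5\) fragments per sample, panel read counts
\(\mathrm{Binomial}(600, \theta/2)\) for 1+Poisson(4) clonal mutations
plus 0–3 subclonal mutations at \(\theta/4\), and logit-normal surrogate
label noise (sd 0.5). Cohort tumour fractions are drawn from
Beta(2, 3.5), a stage-IV-like distribution concentrated above 10%. One
global seed fans out into per-sample substreams, so each sample is
individually reproducible.

Two honest observations about this design. First, the healthy
mono-nucleosome component (sd 9) leaves the 81–125 bp range of
low-tumour samples almost empty, so at \(5\times10^5\) fragments the
Fourier magnitudes of *sampled* histograms are shot-noise limited: the
planted oscillation is cleanly visible in the Fourier features of the
noise-free mixture densities (correlation with θ up to 0.98), but on
sampled histograms the strongest θ-correlated features are coarse
wavelet coefficients (|r| ≈ 0.95), and pipeline runs typically select
those. Second, the generator omits GC bias, library-preparation batch
effects, inter-patient fragmentation differences, and per-cancer-type
signatures; passing tests therefore demonstrate the statistical
machinery recovers a planted relationship under its own assumptions, not
that the defaults reproduce any particular patient cohort.

Problem sizes in the test suite are chosen to exercise each stage
meaningfully while staying desk-scale: cohorts of 41 + 71 samples and a
6-point dilution series for the end-to-end experiment (matching the
defaults), 12 + 40 samples for orchestration tests, 500 observations for
parameter recovery, 20 replicates for the null-selection budget, and
mutation sets of 3–8 at depth 600–1000 for label recovery.

## Known limitations

* The label pipeline assumes heterozygous clonal SNVs in copy-number
  neutral regions; whole-genome doubling or subclonal copy-number
  changes would bias the doubling rule.
* The "annotated" flag on mutations is caller-supplied; the package
  defines only its effect (the fallback rule), not its provenance.
* Only the mean submodel is boosted; precision is global. Heteroscedastic
  extensions (boosting \(\phi\) as well) are out of scope.
* Fragment profiles are protocol-sensitive; models should only be
  applied to data harmonized with their training distribution.
* The periodized wavelet boundary mixes the two window ends; features at
  the first locations of each scale partly reflect that wrap-around.
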