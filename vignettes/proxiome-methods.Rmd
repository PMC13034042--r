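---
title: "Quantifying proximity-labelling screens and ribosome occupancy with proxiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proximity-labelling screens and ribosome occupancy with proxiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxiome)
```

## The problem

TurboID/BioID proximity labelling marks, with biotin, the proteins that
reside within roughly 10 nm of a ligase-fused bait. After streptavidin
capture and mass spectrometry, each purification yields a protein-group
table of iBAQ intensities. The analytical question is which proteins are
*selectively* enriched in a bait purification relative to localization-
matched ligase-GFP controls — the bait's "proxiOME". proxiome implements
that quantification layer, together with two companions used in the same
experimental programme: a polysome-anchored occupancy statistic for
sucrose-gradient western blots (what fraction of free 60S ribosomal
subunits carry a given ribosomal protein), and the sequence-level
computations used to characterize candidate chaperones (isoelectric point,
molecular mass, nuclear-localization-signal consensus scans, qRT-PCR
amplicon prediction).

## The enrichment model

Everything starts from a `ProximityExperiment`: a proteins x runs matrix
of non-negative iBAQ values, where a recorded 0 and an absent cell both
mean "not detected" (MaxQuant writes 0 for missing protein groups; the
normalization below explicitly uses only *nonzero* values, which forces
this reading). Three stages follow.

**Median normalization.** Each run's values are divided by the median of
that run's observed (nonzero) values, making runs comparable despite
different labelling efficiency, input amounts or instrument response.
After `medianNormalize()` every run's observed median is 1 (the per-run
certificate is checked to 1e-12). Because the operation is a per-run
scalar division, multiplying any run by a constant before normalization
changes nothing downstream — the invariance the tests verify exactly.

**Left-censored imputation.** Missing values concentrate at low
abundance (detection limits), so missing-at-random imputation would be
biased upward. `imputeMissing()` uses the downshifted-Gaussian scheme
popularized by Perseus: per target run, compute the mean $\mu$ and
standard deviation $\sigma$ (denominator $n-1$) of the log2 observed
values, then draw each missing cell from
$N(\mu - d\sigma,\, (w\sigma)^2)$ in log2 space. The defaults $w = 0.3$,
$d = 1.8$ are the canonical "standard settings" of that software; the
exact version behind any given dataset is rarely recorded, so both are
explicit, configurable parameters and the values used are stored in the
object's metadata. Only designated runs are imputed — by default the
control purifications, never the baits: a protein undetected in a bait
run is simply not scored for that bait, while a protein undetected in a
control still needs a finite reference value for its fold change to be
defined. Draws come from a dedicated seeded stream (proteins in row
order, runs in column order), so results are exactly reproducible and
the caller's RNG state is untouched.

**Enrichment.** For protein $i$ in bait run $b$ with reference runs $R$:

$$\mathrm{enrichment}_i = \log_2 v_{ib} \; - \;
\mathrm{agg}_{r \in R}\, \log_2 v_{ir}$$

with $v$ the normalized values. Three reference schemes cover the designs
supported:

* `paired_controls` — $R$ is the two control runs, `agg` the arithmetic
  mean of the log2 values. "Averaging the controls" does not by itself
  pin the scale of the average; the mean is taken on the log2 scale here
  because the subtraction itself is performed on log2 values, and a
  linear-mean variant is available through `aggregateReplicates()`'s
  machinery if wanted.
* `pooled_median` — for a series of related baits (e.g. dedicated
  chaperones of different ribosomal proteins), $R$ is the two controls
  plus the runs of all *other* baits in the series, aggregated by the
  median; a protein must stand out against the whole series, not just
  against GFP. Pairs of functionally coupled baits can be reciprocally
  excluded from each other's references (`exclusions = list(A = "B",
  B = "A")`), so that a genuine shared partner is not cancelled out.
  With two controls plus an even number of remaining baits the reference
  count is odd, and the median then commutes exactly with the log
  transform.
* `replicate_averaged` — for replicated designs, normalized values are
  averaged on the *linear* scale over non-missing bait replicates and
  non-missing control replicates before the log2 difference. The order
  matters: bait replicates {1, 4} give $\log_2 2.5 \approx 1.32$, not 1.

`summarizeAcrossAssays()` gives the box-plot quantities for a protein's
enrichment across many assays (median, linear-interpolation quartiles —
R's type-7 quantile — min/max, and Tukey 1.5 x IQR outliers; published
boxplots typically flag outliers without stating a rule, so the Tukey
default is used). `rankCandidates()` orders records by
enrichment with deterministic tie-breaking (abundance, then id).

No p-values are computed: with single-run yeast purifications there is no
within-bait replication to test against, and the screen's logic is
selectivity across a series, not significance against a noise model.

## Gradient occupancy

`GradientProfiles` holds 20-fraction band-intensity profiles (gradient
top to bottom) per protein and replicate. The statistic asks: what
proportion of free 60S subunits carry protein X, using protein Y (an
obligatory, early-assembling subunit component) as the denominator?
Absolute blot intensities are not comparable between antibodies or
exposures, so each profile is first divided by its mean intensity in two
polysomal fractions (13 and 14 by default) — anchoring both proteins to
the translating-ribosome population, where co-occupancy is assumed to be
complete. The per-fraction ratio of the two normalized profiles then
estimates relative occupancy directly: 1 in the polysomes by
construction, and the true occupancy $\theta$ wherever a single particle
class dominates a fraction. `replicateStats()` summarizes fraction groups
(60S = fraction 9, 80S = 10-11, polysomes = 13-15) by pooling all
replicate x fraction values (mean, SD with $n-1$; SD = 0 for a single
value). Pooling within the group, rather than averaging per-fraction
means, treats every fraction's ratio as one observation of the group's
occupancy; the per-replicate-mean alternative is available via
`pool = FALSE`. Ratios
with a zero denominator are undefined and excluded, never imputed. The
whole statistic is exactly invariant to scaling either profile, which is
what makes film exposure irrelevant.

## Sequence features

* **Net charge / pI.** Henderson-Hasselbalch: positive groups
  (N-terminus, K, R, H) contribute $1/(1+10^{pH-pK_a})$, negative groups
  (C-terminus, D, E, C, Y) contribute $-1/(1+10^{pK_a-pH})$. The charge
  is strictly decreasing in pH, so the pI is found by bisection on
  [0, 14] (stop at |charge| < 1e-6 or interval < 1e-4); a grid-scan
  oracle confirms agreement to 2e-4. The default pKa set is the
  Bjellqvist set used by the common pI/MW web services — the family most
  consistent with published "calculated pI" values — and is swappable via
  the `PkaSet` class. Computed pI values are method-dependent at the
  ±0.1 level across pKa sets; treat them accordingly.
* **Molecular mass.** Sum of standard average residue masses plus one
  water (18.0153 Da); additive under concatenation up to the condensation
  water.
* **cNLS scan.** The loose classical monopartite importin-alpha consensus
  K-K/R-x-K/R, every overlapping window reported, 1-based inclusive
  coordinates throughout.
* **bPY-NLS scan.** A basic-enriched stretch followed by
  R/K/H-x(2-5)-P-Y/φ, with φ a hydrophobic residue ({L, I, V, F, M, W}
  in addition to Y, the standard PY-NLS usage). "Basic-enriched" is not
  quantified in the motif literature; here it is operationalized as at
  least `min_basic = 4` K/R/H residues in the `window = 20` residues
  immediately before the anchor — parameters chosen once so that a
  26-residue C-terminal segment carrying 11 basic residues (the
  configuration described for the Bcl1-type chaperone signal, and the
  Hrp1-type signal) is accepted while poly-alanine contexts are rejected;
  both are exposed as arguments. Hits record the anchor, P and Y/φ
  positions and whether the signature ends within 3 residues of the
  C-terminus.
* **Amplicon prediction.** Exact, case-insensitive matching of the
  forward primer and of the reverse complement of the reverse primer on a
  linear plus-strand template; every forward/downstream-reverse pair
  yields a product spanning both primers inclusive, sorted by length.
  Mismatch tolerance and degenerate bases are deliberately out of scope —
  the supported use is validating exact-match qRT-PCR designs.

## The synthetic-data generators

Real deposited raw MS data cannot be reduced to desk-scale fixtures, so
validation rests on seeded generators whose ground truth is known.

`simulateTurboidSeries()` emulates the statistical structure the
enrichment analysis assumes: log-normal base abundances (log2 mean 20,
SD 2 — the dynamic range typical of iBAQ tables), per-run scale factors
(uniform on [0.5, 2]), a configured log2 effect $\delta$ for each bait's
proximal set, a bait self-effect, endogenously biotinylated background
proteins boosted identically in every run (they cancel in any reference
scheme — which is exactly why real screens display but ignore them), and
residual log2 noise. Missingness is intensity-dependent, not MCAR:
$P(\text{missing} \mid x) = 1/(1+\exp((\log_2 x - \tau)/s))$, the
left-censored regime that motivates downshifted imputation ($\tau = 16$,
$s = 1$ gives ~5% overall missingness under the default abundance model).
The default design mirrors a single-replicate bait series with two
controls; a replicated mode (3 bait + 6 control runs) serves the
replicate-averaged scheme. Two deliberate design properties:

* Baits and default proximal proteins are placed in the upper quartile of
  the abundance distribution. Positive effects on upper-quartile proteins
  leave every run's nonzero median unchanged, so in the noise-free limit
  the recovered enrichment equals $\delta$ *exactly* — the sharp oracle
  the tests exploit. It is also the realistic regime: baits are
  overexpressed and true neighbours are efficiently labelled.
* Draw order is fixed (abundances, scales, per-run noise, per-run
  censoring), so a seed fully determines the output.

`simulateGradient()` builds the denominator profile as a sum of
compact-support component templates (free pool in fractions 1-4, 60S
peak at 7-9, 80S at 10-12, polysomes 13-20) and the numerator as the
same components scaled by per-component occupancies $\theta$; polysomal
$\theta$ defaults to 1, matching the anchoring assumption. Compact,
non-overlapping supports over the scored fraction groups make noise-free
recovery exact, which pins the estimator's correctness separately from
its noise behaviour. Noise is one multiplicative log-normal draw per
(fraction, replicate), shared by the two profiles: both proteins are
probed from the same lane of the same fraction, so loading and recovery
variation is common-mode and largely cancels in the ratio — the reason
the two-replicate design is informative at all. An independent
per-profile `detection_cv` (default 0) adds antibody/detection noise for
robustness checks.

What the generators do **not** emulate: peptide-level sampling and
protein inference, ratio compression, correlated contaminant structure,
batch effects across series, antibody saturation and blot nonlinearity,
or overlap between particle classes within a gradient fraction. Passing
tests therefore demonstrate that the estimators recover the truth of
this generative model — not that any real dataset satisfies it.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7); medians by the same rule.
* SDs: $n-1$ denominator everywhere; SD defined as 0 for $n = 1$.
* A run with no nonzero values, a target run with fewer than 3 observed
  values, an all-zero reference-fraction window, and an empty reference
  set are hard errors naming the offending run/protein.
* Ties in ranking break by abundance then lexicographic id; tied
  enrichment rows in written tables order by protein id. Written
  enrichment tables carry 6 significant digits.
* Problem sizes used in the shipped checks (chosen to exercise the
  asymptotics the estimators rely on while staying comfortable to run):
  2000-3000 proteins, 5 baits, 10 ranking replicates, 1000 random motif
  sequences, 100 random peptides for the pI oracle.

## Known limitations

* The printed pI/mass values for the specific chaperone proteins can only
  be reproduced against their database sequences; the package ships the
  computations and their oracles, not third-party sequence data.
* `pooled_median` assumes most series members do not share interactors;
  a protein genuinely proximal to most baits in a series is partially
  self-referenced and its enrichment understated.
* The occupancy statistic reads on whatever co-sediments in the scored
  fractions; it cannot distinguish particle subpopulations within one
  fraction.
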