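---
title: "ereflow: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ereflow: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ereflow)
```

# Scope

`ereflow` analyses the interplay between the transcriptome — protein-coding
genes plus endogenous retroelements (EREs: LINE, SINE and LTR class
repeats) — and the MHC class I immunopeptidome (the set of 8–11-mer
MHC-I-associated peptides, MAPs, detected by mass spectrometry). The
pipeline covers differential expression and differential peptide abundance,
ERE class enrichment, peptide physicochemical statistics, peptide-to-RNA
integration through candidate databases and rphm (reads per hundred
million), and cohort-level stratification with ssGSEA, pre-ranked GSEA and
median splits. A synthetic-data generator with planted, recoverable effect
structure replaces the original RNA-seq and mass-spectrometry inputs so
that every stage can be tested end to end on any machine.

This vignette documents the models, the conventions that were genuinely
open, the defaults and their units, and what the synthetic tests do and do
not establish about real data.

# The differential engine

Both transcript counts and peptide intensities are tested with the same
empirical-Bayes moderated t-test (`moderated_test()`), operating on
log2-scale values:

* transcripts: `log2_norm()`, i.e. log2 of median-of-ratios-normalized
  counts on the cpm scale, plus 1;
* peptides: log2(intensity + 1) after detection filtering and imputation.

Per feature, the pooled two-group variance $s^2$ (residual df $d = n_1 +
n_2 - 2$) is shrunk towards a prior with df $d_0$ and location $s_0^2$:

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},\qquad
  t = \frac{\bar x_2 - \bar x_1}{\tilde s\sqrt{1/n_1 + 1/n_2}},$$

with a two-sided p-value from a t distribution on $d_0 + d$ df. The prior
is fitted by method of moments: under the scaled-inverse-chi-squared prior
the marginal law of $s^2/s_0^2$ is $F(d, d_0)$, whose first two moments
give

$$d_0 = \frac{2d + 4Rd - 4}{Rd - 2},\qquad R =
  \frac{\operatorname{var}(s^2)}{\operatorname{mean}(s^2)^2},\qquad
  s_0^2 = \overline{s^2}\,\frac{d_0 - 2}{d_0}.$$

When the observed spread of $s^2$ is at or below the pure
chi-squared expectation ($Rd \le 2$) the prior df is effectively infinite
and is capped at $10^6$, i.e. complete pooling. Setting `model =
list(d0 = 0, s0_sq = 1)` turns moderation off and reproduces the ordinary
equal-variance t-test exactly; the test suite asserts both this limit and
the shrinkage arithmetic on hand-computed cases.

Multiple testing is Benjamini–Hochberg throughout (`bh_fdr()`, a validated
front end to the standard step-up adjustment). Differential calls use the
joint rule *up* $\iff$ log2FC $> \tau_{lfc}$ and $q < \tau_{fdr}$, with
defaults $\tau_{lfc} = 1$ and $\tau_{fdr} = 0.05$; a feature significant by
FDR but below the fold cutoff stays non-significant, matching how volcano
thresholds are conventionally applied in this setting.

## Normalization

`cpm()` is the plain counts-per-million transform (every column sums to
$10^6$) and is the unit used by the cohort ERE metrics. For differential
testing, however, plain library-size normalization is biased by design:
when a treatment strongly induces a block of features (here, hundreds of
ERE loci and cancer-testis genes), treated library sizes inflate and every
null feature acquires a spurious negative fold-change. `log2_norm()`
therefore divides each sample by a median-of-ratios size factor (the median
across features of the ratio to the feature's geometric mean) before
scaling to the cpm range. The test suite constructs exactly this
compositional scenario with a fixed read budget and checks that raw cpm
shows the spurious drop while the normalized values do not.

## Peptide detection and imputation

A peptide enters testing when it is detected in at least 2 replicates of at
least one condition. Remaining missing intensities are imputed with half
the minimum observed intensity of that replicate column — the standard
label-free convention for values missing because they fall below the
detection limit. The rule is isolated in `impute_peptides()` so an
alternative can be swapped in. Condition-specific peptides (detected in
every treated replicate, in no control replicate) are flagged separately by
`call_condition_specific()` and never depend on imputation.

# ERE metrics

* **Class enrichment** compares the class composition of upregulated loci
  to the full annotation's composition; per class, the two-sided binomial
  p-value uses the tail-doubling rule $p = \min(1,\, 2\min(P(X\le o),
  P(X\ge o)))$.
* **Cumulative ERE expression** $E_p$ is the per-sample sum of cpm over a
  fixed ERE set; no transform is applied before summing.
* **HE-ERE count** $H_p$: for each ERE, the reference is the median of its
  cpm over samples with non-zero expression; $H_p$ counts the set's EREs
  strictly above their reference in sample $p$. Strict inequality is
  deliberate ("above the median"), and an ERE expressed nowhere contributes
  to no sample.
* **Median split**: a sample is *high* iff its score is $\ge$ the median.
  On an odd number of distinct scores this places the median sample in the
  high group — 437 distinct scores split 219/218 — which is the convention
  that reproduces the published cohort group sizes.

Biotype assignment for peptides follows the priority *canonical > CTA >
ERE > other-noncanonical*: a peptide is called ERE-derived only when no
protein-coding source explains it. This conservative rule keeps the
ERE-MAP class small, as observed in practice; cancer-testis (CTA) status
comes from a user-supplied id list rather than a hardcoded catalog.

# Peptide-to-RNA integration

Candidate databases are built by three-frame translation of stranded
transcript sequences (six-frame genome-space databases are out of scope):
fragments are split at stop codons and at N-containing codons (translated
as X), and all 8–11-mer windows of every fragment are indexed with their
source, frame and offset. The suite verifies that each emitted peptide is
re-findable at its stated position and that window counts follow
$\sum_{k=8}^{\min(11,L)} (L - k + 1)$.

RNA support for a peptide is quantified as rphm $= r \cdot 10^8 / T$ with
$r$ the reads over the peptide's source regions and $T$ the context's total
reads. The normal-tissue screen flags a peptide–tissue cell when rphm
strictly exceeds 8.55 — the published default of the RNA-support tool this
mirrors, exposed as a configurable threshold, not a law — and a peptide is
"lowly or not expressed" when no context is flagged, with no averaging
across contexts.

Concordance classes (`rna_up`, `rna_down`, `rna_unchanged`, `rna_absent`)
attach each differential peptide to its best-supported source: maximal read
support, ties broken canonical > CTA > ERE > other, then lexicographic id —
deterministic and conservative.

# Gene-set machinery

**ssGSEA** uses expression ranks $r_i$ (largest expression = rank $n$),
in-set weights $|r_i|^\alpha$ with $\alpha = 0.25$, and the running-sum
score $ES = \sum_i [P_{in}(i) - P_{out}(i)]$. The published analyses name
the method but not the variant; the raw (unnormalized) ES is used because
it is the testable core, and it is invariant under any strictly monotone
transform of a sample's expression. The implementation is checked against
a definitional brute-force oracle on all subsets of a small universe.

**Pre-ranked GSEA** uses the classical weighted (exponent 1) running sum
with the maximal-magnitude deviation as ES. The null is gene-label
permutation (random sets of the observed size), because the interface
ingests a pre-ranked statistic rather than replicate matrices. NES divides
ES by the mean magnitude of same-sign null scores; the permutation p-value
is two-sided over all permutations, $p = (1 + \#\{|ES^\ast| \ge
|ES|\})/(n_{perm}+1)$, which is bounded below by $1/(n_{perm}+1)$ and is
verified to be approximately uniform under random sets. Permutation seeds
are explicit arguments and are recorded in the result.

**Over-representation** is the inclusive upper-tail hypergeometric
$P(X \ge k)$ with BH adjustment across sets; for zero overlap this tail is
1 by definition.

**Cohort stratification** scores CD8 T-cell abundance as the mean
log2(cpm+1) of CD8A and CD8B, takes the HE-ERE count as the default ERE
axis (cumulative cpm selectable), median-splits both axes and emits the
four strata. The ranking fed to the stratified GSEA defaults to the
moderated t of CD8-high vs CD8-low samples within a stratum.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline targets, chosen once:

* **Experiment**: 2000 genes + 3000 ERE loci, 3 replicates per group,
  negative-binomial counts with variance $\mu + \phi\mu^2$, $\phi = 0.1$;
  baseline means log-normal (median 50). Planted upregulation
  (log2FC $\sim N(2, 0.5^2)$) hits all 100 cancer-testis genes and 20% of
  LINE+LTR loci; SINE and Other loci receive no effect, mirroring the
  selective inducibility of DNA-methylation-silenced repeat classes. The
  default class mix (LINE .35 / SINE .45 / LTR .15 / Other .05)
  approximates genome-wide RepeatMasker locus proportions.
* **Proteome**: 500 proteins of length 300 with Dirichlet residue
  frequencies around typical vertebrate composition. A 20% subset carries
  the full Dirichlet enrichment factor on Asp and Gly and half the excess
  on Val, so that recovery analyses rank D and G as the top-2 composition
  correlates with Val following — the ordering reported for
  DNMT2-hypersensitive proteins. Peptides from this subset also receive an
  extra up-shift in the immunopeptidome, coupling residue composition to
  up-DEM counts.
* **Immunopeptidome**: 2000 8–11-mers cut from the proteome (plus ~0.8%
  attributed to ERE loci, placed near the detection limit because ERE MAPs
  are rare and low-abundance). Peptide log2FC $= a\,\cdot$ (source RNA
  log2FC) $+ (1-a)\cdot$ independent effect $+$ noise, with RNA drive
  $a = 0.3$ by default — most peptide changes are post-translational, as
  observed. Independent effects are sparse (25% of peptides, sd 2);
  replicate noise is 0.25 log2 units (~18% CV). Detection is
  missing-not-at-random: dropout probability `detect_dropout_scale` ×
  plogis((c − log2 I)/0.5) with c the 10th intensity percentile, giving
  ~8–12% missingness concentrated at the detection limit; scale 0 disables
  missingness. No quantitative missingness figures were published for the
  data this emulates, so these are conventional label-free values exposed
  in the configuration. Under these defaults the differential fraction of
  the immunopeptidome lands in the published 6–23% range.
* **Cohort**: 437 samples. A latent autophagy activity $A_p \sim N(0,1)$
  raises autophagy-set genes (+$A_p$ on log2 means) and lowers ERE loci
  (−`beta_autophagy`·$A_p$); a latent CD8 abundance $C_p = -$`beta_cd8`
  $\cdot A_p + N(0,1)$ drives the CD8A/CD8B markers, encoding the
  observation that high-autophagy blasts are depleted of CD8 T-cell
  infiltration. Expression is returned as counts scaled by one
  cohort-wide factor to the cpm range: per-sample depth variation is
  deliberately not simulated, because per-sample renormalization would
  leak the autophagy-gene shifts into every other feature and confound
  the planted null (`beta_autophagy = 0`) configuration. A vanishing
  continuous jitter (≤ 1e-9) keeps per-sample scores almost surely
  distinct.

Randomness: every stage derives its own stream from the root seed as
(seed + 77003·stage) mod (2³¹−1), so identical configurations give
bit-identical outputs and stages can be regenerated independently.

## What the synthetic tests do and do not show

The generator plants clean, block-structured effects with known truth; it
does not emulate GC or length biases, mappability or multi-mapping of
repeat-derived reads, batch effects, correlated replicate structure,
spectral interference or peptide-level FDR, or MHC binding preferences.
Passing recovery tests therefore demonstrates that the statistical
machinery is correct and calibrated under its stated model — not that the
pipeline overcomes the upstream artefacts of real repeat quantification or
label-free MS. Conversely, the published headline counts (hundreds of
shared up-EREs, specific DEM tallies) derive from the deposited data of
the original study and are not reproducible at this desk scale; the
acceptance machinery checks conventions (219/218 split, rphm = 8.55 at
171 reads per 2×10⁹), oracle equivalences, calibration bands and planted
parameter recovery instead.

# Numerical choices and degenerate inputs

* log offsets: log2(x + 1) for both cpm and intensities, bounded at zero.
* `fit_shrinkage()` needs ≥ 2 finite variances; all-zero variances are an
  error, and near-homogeneous variance maps to complete pooling.
* A zero margin in the C-terminal 2×2 table yields p = 1 with a warning
  rather than an error, since sparse DEM sets are common.
* Constant gene-set scores are excluded from correlation rankings with a
  warning; a constant covariate gives all-NA.
* Median split of constant scores labels every sample high and warns.
* GSEA running-sum ties take the first extreme encountered along the
  ranking.
* `sim_config()` validates fractions, the class-mix simplex (tolerance
  1e-9), cohort size ≥ 4 and non-negative dispersions before any
  simulation runs.

# Problem sizes used by the test suite

Unit tests run on reduced configurations (hundreds of features, 60-sample
cohorts); the acceptance checks use the full default conditions — 5000
features × 6 samples for recovery, 50 null simulations of 2000 features
for type-I calibration, 200 random gene sets × 200 permutations for GSEA
calibration, and the 437-sample cohort — sizes at which every documented
band is met with margin while the whole suite stays interactive.
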