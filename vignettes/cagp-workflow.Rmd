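---
title: "Methods: moderated differential expression, gene programs and NanoString normalization"
author: "cagptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated differential expression, gene programs and NanoString normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagptools)
```

# The scientific setting

Before sex determination, the mouse gonad is a bipotential organ whose
somatic progenitors (SF1+ cells) already transcribe, at low level, much
of the genetic toolkit of both the testicular and the ovarian fates.
`cagptools` implements the computational chain used to characterise that
state from expression data collected over a 2-sex (XX/XY) x 2-genotype
(control vs *Insr*;*Igf1r* double-knockout, "dko") x developmental-stage
design:

1. moderated differential expression between condition pairs that vary
   exactly one factor;
2. construction of the **core adreno-gonadal program** (CAGP): genes
   up-regulated at least 1.5-fold between E10.5 and E11.5 in *both*
   sexes;
3. overlap of the CAGP with sexually dimorphic, externally defined
   "primed", and mutant-down-regulated gene sets, with hypergeometric
   overlap statistics and simple percentage arithmetic;
4. a complete NanoString nCounter count-processing chain (background
   correction, positive-control QC, geNorm reference selection,
   geometric-mean normalization) followed by a per-gene
   sources-of-variation ANOVA.

Because the original array data live in public repositories and are not
required here, a first-class simulation module generates inputs with
planted ground truth, and every downstream claim in this package is a
statement about recovery of planted structure.

# The moderated differential-expression test

For a two-condition comparison with $n_A$ and $n_B$ replicates, each
probeset $g$ yields condition means, the pooled residual variance
$s_g^2$ on $d_g = n_A + n_B - 2$ degrees of freedom, and
$\log_2 \mathrm{FC} = \bar{x}_B - \bar{x}_A$. Variances are shrunk
toward a scaled inverse-chi-square prior with hyperparameters
$(d_0, s_0^2)$ estimated by moment matching on the log variances: with

$$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2),$$

$d_0$ solves $\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}$
(monotone bisection, relative tolerance $10^{-8}$, root capped at
$10^8$ before being declared unbounded) and
$s_0^2 = \exp\{\bar{e} + \psi(d_0/2) - \log(d_0/2)\}$. When the
log-variance scatter does not exceed its sampling component the
equation has no positive root; $d_0$ is then reported as `Inf` and
$s_0^2$ is the arithmetic mean of the variances, the natural scale of
the limiting point-mass prior (this also makes the all-identical
degenerate case return the common value). Zero variances carry no
information about the prior on the log scale and are excluded from the
moment fit but still receive a posterior variance. The test statistic is

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\log_2 \mathrm{FC}}{\tilde{s}_g\sqrt{1/n_A + 1/n_B}}$$

against $t_{d_0+d_g}$ (a normal reference when $d_0$ is unbounded).
$d_0 = 0$ is accepted and reproduces the ordinary pooled t-test
exactly, which the tests exploit as an analytic limit.

A probeset is retained as differentially expressed when all three hold:

* **intensity** — the larger condition mean is *strictly* above the
  intensity floor (by default the global median of the whole matrix;
  the rule evaluates condition means, not individual replicates,
  because the fold-change rule is likewise defined on averaged values);
* **fold change** — $|\log_2 \mathrm{FC}| \ge \log_2 1.5$, boundary
  inclusive;
* **significance** — Benjamini–Hochberg adjusted $p \le 0.01$
  (adjustment over all probesets of the comparison, before any other
  filter).

Each pairwise comparison is fit independently — moderation pools
information across probesets within one comparison, never across the
four comparisons — because the analysis is defined as four standalone
pairwise contrasts rather than one joint linear model.

# Program construction rules

**CAGP.** Probesets significantly up-regulated between the first two
stages (default E10.5 vs E11.5, taken directly; the intermediate E11.0
timepoint present in some time courses is deliberately skipped) in both
the XX and the XY control contrast. Collapse to genes keeps a gene when
at least one of its probesets is a member and drops it as
*contradictory* when its annotated probesets are significantly
regulated in both directions in the adjudicating table. The
significance-based reading of "contradictory expression profile" is a
design choice (a sign-of-mean rule would also be defensible); it is
recorded in each program's provenance string. When two tables are
available (one per sex) a gene removed against either is removed.

**Dimorphic sets.** A probeset is male-dimorphic when the sex contrast
(XX as condition A, XY as condition B, so positive fold change means
XY-up) is significant at one or more stages at or after the onset stage
(default E12.5) and never significant in the opposite direction at any
such stage; female-dimorphic symmetrically; conflicts go to neither.
The onset default reflects that sex-specific expression is established
after E11.5.

**Overlaps.** For programs $A$ and $B$ in a universe of $N$ genes, the
observed intersection is compared with $|A||B|/N$ and with the
hypergeometric tails $P(X \ge k)$ and $P(X \le k)$. Percentages are
plain ratios ($100 k/|A|$), optionally rounded to the nearest integer —
the same arithmetic used for the published program counts (e.g. 141 of
596 is 23.66%, printed as "more than 23%"). Term enrichment applies the
identical hypergeometric machinery per annotation term with BH
adjustment across terms, separately for over- and under-representation.

**Clustering.** The expression-profile clustering method is Euclidean
K-means with ten seeded restarts (best by total within-cluster sum of
squares); agglomerative complete-linkage clustering is offered behind a
method flag, since descriptions of "K-means (complete linkage)"
conflate the two families and both readings deserve a reproducible
implementation.

# NanoString chain

* **Background**: per sample, threshold = mean + 2 SD of the
  negative-control counts (sample SD, $n-1$ denominator — the estimator
  is a convention, not specified by the protocol); subtracted from all
  counts, results below 1 fixed to 1; negatives then dropped.
* **QC**: per-sample average of the positive-control *raw* counts (QC
  precedes background correction); the run passes when max/min of the
  averages is below 3. The plain mean over spike levels is used.
* **geNorm**: candidate stability
  $M_j = \mathrm{mean}_{k \ne j}\, \mathrm{SD}_s\,
  \log_2(c_{js}/c_{ks})$; iterative exclusion of the worst candidate
  with recomputation each round, down to a final pair, ties broken by
  probe id order. The k = 6 longest survivors are the reference set
  (k is fixed by the study design; the original pairwise-variation
  statistic $V_{k/k+1}$ is computed and reported but does not drive
  selection).
* **Normalization**: per-sample geometric mean $g_s$ of the reference
  counts; every count is multiplied by $\bar{g}/g_s$ with $\bar{g}$ the
  arithmetic mean of the $g_s$, keeping output on a count-like scale.
  Note a consequence of the rescale constant: rescaling one sample's
  raw counts cancels only *up to a single global constant* shared by
  all entries (the constant is a data-wide mean, so it moves too);
  every within- and cross-sample comparison is preserved exactly, and
  the test suite asserts exactly that form of invariance.
* **ANOVA**: per gene, $\log_2$(normalized count) on stage + genotype +
  sex, main effects only (the three-way layout names three sources, and
  interaction terms would be poorly supported at 3 replicates per
  cell). Sums of squares are sequential in the order stage, genotype,
  sex; the simulated designs are balanced, where all SS types coincide
  and component plus residual SS equal the total. Whether the original
  analysis log-transformed is unrecorded; the log2 response is this
  package's convention and is flagged here.

# What the simulator emulates — and what it does not

`simulate_expression()` plants five gene classes (null, cagp,
dimorphic-male, dimorphic-female, primed) on a log2 scale with additive
Gaussian noise, over the full 2 x 2 x stage x replicate design.
Defaults, chosen once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_probesets` | 2000 | desk-scale analogue of a genome-wide array |
| class proportions | 0.15 / 0.05 / 0.05 / 0.05 | planted-signal benchmark scale: large enough classes for stable recovery estimates at a few thousand probesets |
| `cagp_dimorphic_fraction` | 0.5 | about half of the core program later becomes dimorphic (281/596 in the real data) |
| `dko_attenuation` | 0.30 | a substantial minority of program genes lose their effects in mutants, matching the reported ~23–33% range |
| `effect_size` | log2(2) = 1 | one twofold step, comfortably above the 1.5-fold filter |
| `noise_sd` | 0.25 (log2) | replicate variance of the real arrays is unpublished; this is a free parameter representing a well-behaved sorted-cell array experiment, not an estimate |
| `replicates` | 3 | three independent RNA pools per condition, as in the study |
| stages | E10.5, E11.5, E12.5, E13.5 | the profiled window; E11.0 omitted from the default design |

Non-null genes draw baselines from the upper half of the baseline
distribution (`baseline_mean + |N(0, baseline_sd)|`): gene programs are
by construction defined over expressed, above-median transcripts, so
planted program genes are placed where the intensity filter can in
principle see them. Attenuation is effect *removal* in the mutant (means
revert to baseline), not a sign flip, because mutant effects on program
genes are reported as down-regulation. Primed genes are modelled as a
constant both-sex elevation at all stages plus a later sex effect, so
attenuated primed genes are visibly down in mutants at E11.5 while
dimorphic-only genes (no E11.5 effect) are not — attenuation of the
latter is invisible at E11.5 by design.

`simulate_nanostring()` draws biological probes as negative binomial
(dispersion 0.1) around abundance x size-factor means with additive
Poisson background; positive spike-ins are near-Poisson technical
controls independent of the content size factor (so the QC ratio stays
below 3 in a default run, as in a passing experiment), and
`dispersion = 0` switches the whole generator to deterministic counts
`round(mu + background)`, which the exact zero-noise tests rely on.

Deliberately **not** emulated: probe-level hybridization physics and
CEL-file summarization (inputs are already-summarized log2 matrices; a
quantile-normalization stand-in is provided), cell-sorting artefacts,
correlated noise between probesets of one gene, batch structure, and
any real gene identity — annotations and term labels are synthetic.
Passing recovery tests therefore demonstrate that the chain implements
its rules correctly and recovers planted structure under its stated
noise model; they say nothing about biological validity on real arrays
beyond that.

# Numerical and degenerate-input conventions

* Even-count median = mean of the two middle order statistics.
* Trigamma inversion by bisection at relative tolerance $10^{-8}$;
  roots above $10^8$ reported unbounded.
* Zero residual variance: excluded from moment estimation, flagged,
  posterior variance still assigned; a fold change over zero posterior
  standard error yields $t = \pm\infty$ ($t = 0$ when the fold change
  is also zero). An all-zero-variance comparison is an error — with no
  replicate scatter anywhere there is nothing to moderate.
* KL similarity uses 64 equal-width bins over the pooled range with a
  0.5-count smoothing pseudocount per bin (finite divergences on finite
  samples); the unsmoothed two-distribution primitive is exported
  separately and matches hand summation, returning `Inf` where an
  absolutely-continuous assumption fails. The binning behind the
  original distance matrix is unrecorded; both bin count and
  pseudocount are parameters.
* Correlation similarity for a constant sample is `NA` with a warning
  naming the sample, never silently 0.
* geNorm ties (including the final pair) resolve by probe id order so
  the exclusion order is a deterministic function of the input.
* All TSV output uses 12 significant digits; reruns of the pipeline on
  identical inputs are byte-identical (the expression pipeline itself
  consumes no randomness).

# Problem sizes used by the test suite

Recovery properties run on 2000-probeset simulations (48 samples) over
20 seeds, the scale at which class counts are stable; oracle-equivalence
properties run on at least 100 random instances each against
brute-force implementations (step-up BH by rank scan, hypergeometric
tails by subset enumeration at universe sizes up to 12, geNorm by
direct all-pairs recomputation at up to 8 candidates). The
empirical-Bayes fit is checked both against its own moment equations
via an independent root-finder and against `limma`'s reference
implementation, which is used only as a cross-check, never as the
implementation.

# Known limitations

* The four-comparison design moderates variances per comparison; if the
  original analysis pooled across all conditions jointly, its q-values
  would differ slightly. The per-comparison reading follows the
  description of four standalone pairwise comparisons.
* The published gene counts (2147 affected probesets, 596 CAGP genes,
  …) depend on the deposited accession data and are not reproduced at
  simulation scale; the package reproduces the *arithmetic* on the
  printed counts and the *behaviour* of the chain on planted data.
* Sequential ANOVA SS are order-dependent on unbalanced designs; the
  declared order (stage, genotype, sex) is part of the method.
* The hypergeometric enrichment treats genes as exchangeable; no
  gene-length or expression-level bias correction is attempted.
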