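---
title: "Methods: cfDNA fragmentomics, nucleosome phasing and composition in cfphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics, nucleosome phasing and composition in cfphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfphase)
```

# Scope

Circulating cell-free DNA (cfDNA) is released mainly by dying cells as
nucleosome-protected chromatin fragments and then degraded by plasma
nucleases and cleared by the liver. Several orthogonal layers of
information survive this process: the fragment length distribution, the
nuclease cut-site sequence preferences visible at fragment ends, the
nucleosome positioning of the tissues of origin, the methylation profile
of the contributing cell types, and non-human (microbial) reads. `cfphase`
implements one analysis track per layer, plus a synthetic-data generator
that produces inputs with the statistical structure each analysis assumes,
so the whole toolkit can be exercised and validated end to end without
access to patient data.

# Fragmentation statistics

Fragments are genomic intervals (BED3 input, 0-based half-open; `GRanges`
internally). Lengths are tabulated exactly, and size classes use the
operational boundaries: subnucleosomal < 120 bp, mononucleosomal 120-250
bp, dinucleosomal 251-420 bp, polynucleosomal > 420 bp, all edges
inclusive as stated. The boundaries are exposed as arguments because the
mononucleosome mode sits near 165-167 bp and different studies draw the
mono/di boundary at 220 or 250 bp; the defaults here follow the
operational definition used for computation rather than descriptive
ranges.

The fragmentation index is the ratio of the counts at the two modal
lengths,

$$\mathrm{FI} = \frac{\#\{\text{fragments of length } 167\}}
                    {\#\{\text{fragments of length } 334\}},$$

computed on raw counts at those exact lengths. A `peakMode` variant
instead takes the maxima of the histogram inside the mono and di ranges;
it is useful at low depth, where the count at exactly 334 bp can be zero
and the exact-length FI is undefined (the result then reports an explicit
undefined state rather than dividing by zero). Group contrasts report both
the Welch t-test and the Wilcoxon rank-sum test and let the caller choose.

# Fragment end motifs

Plasma nucleases (DNASE1L3, DFFB, DNASE1) cut with sequence preferences
that leave a signature in the 4-mers at fragment ends. For each fragment
the 5' motif is the reference sequence at its first four bases; the 3'
motif is the reverse complement of its last four bases, so both are
reported 5'-to-3' as the true overhang sequences before end repair. Motifs
overlapping an N, and ends falling outside the reference, are excluded
from the 256-motif support rather than bucketed.

Both ends of a fragment are pooled into a single per-sample frequency
vector. Pooling is a deliberate choice: each double-stranded fragment
carries one 5' terminus on each strand, and nothing distinguishes them
biologically; per-end tables remain available via `perEnd = TRUE`.

The expected baseline is the exact sliding-window 4-mer frequency of the
genome counted on **both strands** (forward sequence plus reverse
complement), because fragment ends sample both strands; a forward-only
mode exists for comparison with single-strand counters. Differential usage
between groups uses a two-sided Wilcoxon rank-sum test per motif with
Benjamini-Hochberg correction across motifs, and log2 fold changes guard
against zeros with a pseudo-frequency of half the smallest nonzero
frequency in the table. Covariate screens use Pearson correlation with BH
correction, dropping missing covariate values pairwise.

# Windowed protection scores

Nucleosome-bound DNA is protected from nuclease cleavage, so fragment
endpoints concentrate in linkers. The windowed protection score at a
position $p$ counts fragments fully spanning a 120-bp window centred at
$p$ minus fragments with at least one endpoint strictly inside it.
Profiles are computed per gene over a 5-kb span centred on the TSS, only
from mononucleosomal fragments (length 120-200 bp inclusive).

Conventions that the sources leave open, fixed here and tested:

* the window is **centred** on the evaluated position, `[p - 60, p + 60)`
  in 0-based half-open coordinates (the window anchor is exposed through
  the `window` argument rather than hard-coded);
* a fragment start equal to the window start counts as
  spanning-compatible, not as an interior endpoint (half-open tie rule);
* minus-strand profiles are mirrored so positive distances always point
  downstream in the direction of transcription.

Raw profiles are adjusted for coverage by subtracting the span mean, then
smoothed with a Gaussian kernel of SD 30 bp. The kernel is truncated at
plus or minus 4 SDs and renormalised over the available support at the
span edges; reflection was the alternative, but renormalisation neither
invents signal beyond the span nor attenuates edge values, and the fit
region used downstream stays far from the edges either way. Gene-set
profiles average the per-gene smoothed tracks (genes with no fragment near
their span are dropped and the retained count recorded) and carry a 95%
confidence band of mean plus or minus 1.96 standard errors across genes.
Per-gene averaging, rather than pooling fragments before scoring, is what
makes that cross-gene confidence band meaningful.

The scoring itself runs in $O(F + P)$ with difference arrays; the test
suite pins it against a literal $O(F \times P)$ counter on random
instances, exactly.

# The nucleosome phasing model

Downstream of an active TSS the +1 nucleosome is well positioned and
phasing decays with distance. The aggregated WPS profile is modelled as

$$\mathrm{WPS}(d) = e^{-\kappa d}
   + A\, e^{-\lambda d} \cos(\omega d - \varphi) + b,$$

with $d$ the signed distance from the TSS in bp: an exponential trend
(decay constant $\kappa$, 1/bp) plus a damped harmonic oscillator with
amplitude $A$ (WPS units), amplitude decay $\lambda$ (1/bp), angular
frequency $\omega$ (radians/bp, period $2\pi/\omega$), phase $\varphi$,
and offset $b$. The first term carries no amplitude coefficient, so for
$d < 0$ it rises above 1; the model is fitted exactly as written over
$d \in [-185, 925]$ bp, which covers the nucleosome-free region and the
first five downstream nucleosomes. The NFR dip is absorbed by this trend
term together with $b$.

Fitting is a two-stage non-linear least squares: the exponential trend
$e^{-\kappa d} + b$ first, then the oscillator on the stage-1 residuals.
Numerical choices:

* stage-2 starts: $\omega_0 = 2\pi/185$, $\lambda_0 = 10^{-3}$,
  $A_0 = \max|\text{residual}|$, with a multi-start over
  $\varphi_0 \in \{0, \pi/2, \pi, 3\pi/2\}$ because the cosine makes the
  objective multimodal in phase; the best residual sum of squares wins and
  ties go to the smallest $\lambda$;
* box bounds keep the period in a biophysically meaningful 80-400 bp band
  ($\omega \in [2\pi/400, 2\pi/80]$) and $\kappa, \lambda \in [0, 0.1]$;
* Levenberg-Marquardt with relative objective tolerance $10^{-8}$ and a
  10,000-evaluation cap; optimiser failure returns a fit object with
  `converged = FALSE`, never an error;
* $A$ is sign-normalised to $A \ge 0$ by shifting $\varphi$ by $\pi$, and
  $\varphi$ is wrapped to $[0, 2\pi)$;
* $b$ is estimated in stage 1, as the asymptote of the trend.

Staged fitting converges reliably but leaves a small bias: stage 1 sees
the oscillation as unmodelled structure and leaks part of it into
$\kappa$ and $b$. A final joint least-squares pass over all six
coefficients, initialised at the staged estimates (`polish = TRUE`, the
default), removes the bias while keeping the staged procedure in its role
as a convergence aid; on noiseless model-generated profiles the polished
fit recovers every parameter to well under 1%. Setting `polish = FALSE`
reproduces the strict staged estimates.

Cohort summaries (coefficient of variation per parameter, period
median/mean/SD) use converged fits only, and parameter-covariate screens
(Pearson with BH correction) drop non-converged fits pairwise. The derived
period is reported alongside $\omega$.

# Methylome deconvolution, genome equivalents, turnover

A reference atlas is a regions-by-cell-types matrix of methylation
proportions. Mixture estimation is nonnegative least squares of the
sample vector on the atlas columns with a **free intercept**, followed by
renormalisation onto the simplex. The intercept (implemented by centering
sample and columns, which is equivalent for an unconstrained offset)
absorbs methylation signal that is uniform across the reference regions
-- notably the background contributed by cell types absent from the
reference -- instead of forcing it into the coefficients; robust
partial-correlation estimators used for this task regress with an
intercept for the same reason. An optional Huber reweighting
(`robust = TRUE`) shrinks the influence of outlying regions. Atlas/sample
region mismatches are resolved by intersection, with the dropped count
reported; near-collinear atlases are flagged via the condition number.

Hierarchical deconvolution follows the two-step contract: the tissue
atlas is augmented with one "immune cells" column -- the weighted average
of the immune atlas columns, weighted by each type's average proportion
in whole blood (a user input; the weights are normalised to sum 1) --
and the sample is deconvolved against this merged reference. The immune
fraction is then split by a second deconvolution against the immune
atlas, and the final vector (tissues plus immune fraction times immune
split) sums to 1. Proportions are simplex-normalised at both steps.

Genome equivalents convert composition into absolute cell-death numbers:

$$\mathrm{GEQ/ml} = p_i \times \mathrm{purity} \times
   \frac{\mathrm{yield\ [ng/ml]}}{0.006\ \mathrm{ng/genome}},$$

and cellular turnover is GEQ/ml divided by circulating cells/ml from a
complete blood count; a ratio of 1 marks equality of cell death and
standing population.

# Microbial signals

Genus read counts (e.g. from a Kraken2 report, for which a genus-level
flattener is provided) become abundances by dividing by the sample's
total non-human reads. Entries under 10 reads are non-detections: they
are excluded from the abundance support, and the denominator is never
recomputed after filtering. The outlier filter pools every detected
(sample, genus) abundance in the cohort into a single distribution --
one distribution, one cutoff -- and flags entries at or above the mean
plus 3.5 SD; a per-genus mode and a log10-scale mode are available behind
flags, but the default operates on raw abundances. Differential abundance
uses Wilcoxon rank-sum with BH correction, treating genera absent after
the read filter as abundance 0 in group tests (absence is informative)
while still excluding them from the pooled outlier distribution. Culture
concordance compares the confirmed fraction among flagged versus
background signals with a two-sided Fisher exact test; the reported odds
ratio is Haldane-corrected (+0.5 per cell) when any cell is zero.

# The synthetic-data generator

The generator is a first-class module, not a test fixture: its defaults
are the study conditions the analyses assume.

* **Genome**: i.i.d. bases, default 41% GC, single chromosome (nothing in
  the methods depends on chromosome count; multi-chromosome inputs are
  supported downstream).
* **Genes**: TSSs with at least 6 kb pairwise spacing (so 5-kb windows
  never overlap) and 2.5-kb flanks, strand about 50/50, an activity
  label per gene.
* **Fragments**: active genes receive ten nucleosomes, the $n$-th centred
  at TSS $+ 100 + n \times 187$ bp in the transcription direction (the
  100-bp offset is a nucleosome-free-region width surrogate; the 187-bp
  repeat matches the spacing of promoter-proximal nucleosome arrays).
  Each fragment's centre is jittered with SD $(5 + 2n)$ bp, so phasing
  decays with nucleosome index -- the mechanism is our stand-in for
  phasing decay, not calibrated to any cohort. Fragment lengths are
  167 +/- 5 bp (Gaussian, rounded). Background fragments are uniform over
  the genome with a class mixture of 3.4% sub / 90.8% mono / 5.2% di /
  0.6% poly, matching the composition of real plasma; inactive genes see
  background only, the random-arrangement control.
* **End bias**: with `ccEndBias` $> 1$ the fragment set is
  importance-resampled, multiplying the sampling odds of fragments whose
  reference 4-mer at the start begins "CC", emulating DNASE1L3-style
  cleavage preference.
* **Methylation**: atlases give each cell type 20 private hypomethylated
  markers (0.05) on a 0.85 background; samples are convex combinations of
  atlas columns plus truncated Gaussian noise clipped to [0, 1].
* **Taxa**: multinomial contaminant backgrounds with planted pathogen
  signals taking a fixed share of a sample's non-human reads.

Every generator is a pure function of its configuration and seed.

What passing on these inputs does *not* show: real cfDNA has GC- and
mappability-structured coverage, correlated (not i.i.d.) noise along the
genome, overlapping genes, chromatin heterogeneity across cell types, and
methylation atlases with correlated, noisy markers. Recovery of the
generative truth here validates the machinery and its conventions, not
cohort-level biology.

# Problem sizes and runtime

The validation suite runs the fragment-to-fit pipeline at 500 active
genes with 50 fragments per nucleosome on a 3.2-Mb genome (250,000
fragments), 21-profile cohorts for direct model recovery, 100 random
instances for the exact WPS oracle, 20-seed recovery loops for
deconvolution and differential tests, and 50-seed null calibrations;
these sizes give stable estimates for every recovery check while keeping
the full suite around half a minute on one CPU.

# Known limitations

* The exponential trend term has unit amplitude by construction, so the
  model cannot represent profiles whose trend at $d = 0$ differs much
  from $1 + A\cos\varphi + b$ WPS units; aggregated profiles with large
  dynamic range rely on $b$ and the oscillator to compensate.
* The synthetic phasing decay (jitter growth) is one of many mechanisms
  that produce decaying oscillations; $\lambda$ estimated on synthetic
  data should not be compared numerically to cohort estimates.
* Deconvolution validation uses well-separated synthetic markers; real
  atlases are noisier and partially collinear, where the robust mode and
  the condition-number flag matter more.
* The microbial module consumes classifier output as given; classifier
  error and contaminant curation are upstream concerns.
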