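# cfphase

Analysis of the circulating cell-free DNA (cfDNA) "circulome" for R:
fragmentomics, fragment end motifs, nucleosome footprinting with a
quantitative phasing model, methylome deconvolution with cellular-turnover
estimation, and microbial signal detection. The package targets
researchers working with plasma cfDNA sequencing (e.g. in sepsis, liquid
biopsy or transplant monitoring) who need the downstream statistics after
alignment and read counting are done. A synthetic-data generator with the
statistical structure these analyses assume makes every method executable
and verifiable without patient data.

## What it computes

* **Fragmentation** — length histograms; size-class proportions
  (subnucleosomal < 120 bp, mononucleosomal 120–250 bp, dinucleosomal
  251–420 bp, polynucleosomal > 420 bp); the fragmentation index
  FI = count(length = 167) / count(length = 334); group contrasts
  (Welch t and Wilcoxon).
* **End motifs** — 5′-oriented 4-bp motifs at both fragment ends,
  observed frequencies against the genome's exact both-strand 4-mer
  baseline, Wilcoxon/BH differential usage, Pearson/BH covariate screens.
* **Nucleosome footprinting** — windowed protection scores (WPS): for
  each position in a 5-kb TSS-centred span, fragments fully spanning a
  centred 120-bp window minus fragments with an endpoint inside it, from
  mononucleosomal (120–200 bp) fragments; mean adjustment, 30-bp Gaussian
  smoothing, strand-aware gene-set averaging with 95% confidence bands.
* **Nucleosome phasing** — the aggregated profile is fitted with

  ```
  WPS(d) = exp(-kappa d) + A exp(-lambda d) cos(omega d - phi) + b
  ```

  by two-stage non-linear least squares (exponential trend first, damped
  oscillator on the residuals, multi-start phase, joint polish) over
  d ∈ [−185, 925] bp; the derived period 2π/ω estimates the nucleosome
  repeat length. Cohort utilities: per-parameter coefficients of
  variation, period summaries, covariate correlations.
* **Composition** — hierarchical reference-based methylome deconvolution
  (tissue atlas + whole-blood-weighted "immune cells" column, then an
  immune split), genome equivalents GEQ/ml = p·purity·yield/0.006, and
  cellular turnover GEQ/ml ÷ cells/ml.
* **Microbial cfDNA** — genus abundances (≥ 10-read detection filter),
  a pooled mean + 3.5 SD outlier filter, Wilcoxon/BH differential
  abundance, Fisher-exact culture concordance.

## Worked example

Simulate a sample with phased nucleosome arrays and run the footprinting
track end to end:

```r
library(cfphase)

cfg    <- simConfig(seed = 7, genomeLength = 1e6L, nGenes = 100L,
                    fragmentsPerNucleosome = 40L, backgroundRate = 0.01)
genome <- generateGenome(cfg)
genes  <- generateGenes(cfg, genome)
frags  <- simulateFragments(cfg, genes, genome)   # 28,400 fragments

h <- lengthHistogram(frags)
round(classifySizes(h)$proportions, 3)
#>  subnucleosomal mononucleosomal   dinucleosomal polynucleosomal
#>           0.011           0.968           0.019           0.002

fragmentationIndex(h)$value
#> [1] 260.17

prof <- wpsGeneSetProfile(frags, genes[genes$activity == "active", ])
fit  <- fitTwoStage(prof)
fit
#> OscillatorFit (converged)
#>   kappa=0.02409 A=30.09 lambda=0 omega=0.03343 phi=3.221 b=-21.74
#>   period=187.9 bp, rmse=9.083 over 1111 points in [-185, 925]
```

The size-class table shows a mononucleosome-dominated mixture, and the
FI of 260 reflects the strong excess of ~167-bp over ~334-bp fragments in
this nucleosome-rich simulation. The fitted period of 187.9 bp recovers
the 187-bp nucleosome repeat the generator placed downstream of active
TSSs; on inactive genes the same fit finds no credible oscillation.

`runDemo(seed)` wires all five tracks into one cohort-level report
(patients vs controls with FI contrast, differential motifs, phasing
fits, deconvolution recovery, and a planted pathogen flagged by the
outlier filter), and `inst/scripts/cfphase.R` exposes the same
functionality as shell subcommands
(`simulate`, `fraglen`, `endmotifs`, `wps`, `oscfit`, `microbes`,
`demo`).

## Documentation

The methods vignette (`vignettes/cfphase-methods.Rmd`) describes the
models, every tunable with units and defaults, the numerical choices in
the oscillator fit and deconvolution, what the synthetic generator does
and does not emulate, and known limitations.
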