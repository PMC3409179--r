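# spikecal

Spike-in based analysis of systematic sequencing errors (SSEs) and base
quality score recalibration (BQSR), with a fully simulatable ground
truth.

## The problem

Systematic sequencing errors concentrate at particular reference sites,
strands and sequence contexts, so at high depth they masquerade as
low-fraction variants. BQSR replaces reported Phred qualities with
empirical ones per covariate cell (read group, reported quality RpQS,
machine cycle, dinucleotide context), but training it on genome-mapped
reads counts every variant absent from the SNP database as an error —
biasing qualities down exactly where variants occur, worst at
hypermutable CpG dinucleotides. Training on synthetic spike-in standards
of certified purity removes that bias and needs no SNP database.

`spikecal` implements the full stack for R users who want to study or
teach this machinery:

* **Reference & pools** — `generate_reference()` builds ERCC-style
  plasmid sets (random inserts in a shared vector backbone);
  `assign_concentrations()` makes equimolar or wide dynamic-range pools
  (log-uniform, endpoints pinned so max/min is exact).
* **Simulators** — `error_model()` defines the generative truth
  `p = 10^-(q + offsets)/10` with per-quality, per-cycle,
  per-dinucleotide and per-site (SSE) offsets; `simulate_reads()` emits
  substitution-only aligned reads with a truth sidecar;
  `simulate_count_tables()` simulates covariate tables directly at
  multi-million-read scales; `inject_variants()` plants CpG-biased,
  transition-biased biological variants.
* **Pileup** — `pileup()` collapses reads to per-position base counts
  stratified by strand and quality tier (SAM in/out supported).
* **Purity certification** — `purity_posterior()` gives the
  beta-binomial posterior probability that a base is ≥99% pure;
  `classify_bases()` applies it across six strand/quality modes and
  multiple platforms and `write_exclusion_vcf()` emits the mask.
  With a flat prior, `min_coverage_for_confidence(0.99, 0.95)` = 298:
  under ~300x coverage no base can be certified.
* **Recalibration** — `bqsr(reads, ref, mask)` fits the hierarchical
  delta decomposition (global → per-quality → parallel cycle and dinuc
  corrections, empirical quality `-10*log10((e+1)/(n+2))` capped at 60)
  and supports `coef()`, `predict()` (recalibrate reads),
  `residuals()`, `summary()`, `plot()`.
* **Evaluation** — split-half `weighted_mad()` of empirical qualities,
  read/reference downsampling, `nucleotide_change_rates()` with Ti/Tv
  (0.5 under uniform random errors), paired pooled-variance t tests and
  per-cell binomial likelihood-ratio tests.

## Worked example

```r
library(spikecal)
fx <- demo_fixture(seed = 1)   # 4 standards, 60k reads, variants, pileup, purity calls
table(fx$calls$verdict)
#>     ENDSKIP high_purity      impure
#>         560        1059          11

mask <- fx$calls[fx$calls$verdict != "high_purity", c("id", "pos")]
fit <- bqsr(fx$reads, fx$ref, mask = mask)
fit
#> Base quality score recalibration fit
#>   observations: 2221269   errors: 5578 (empirical Q26.00)
#>   mean reported quality: 31.60   global delta: -5.597

round(coef(fit)$dinuc["32", c("GG", "GC", "AC", "TA")], 2)
#>    GG    GC    AC    TA
#> -3.87 -1.66 -1.87  1.05
```

Reading the output: 1059 insert-interior bases reach >95% posterior
probability of ≥99% purity and form the training set; the 11 impure
bases are the injected variant sites. The fitted instrument really is
miscalibrated (empirical Q26 against a mean reported Q31.6), and the
dinucleotide deltas at Q32 reproduce the simulated pattern — GG worst,
GC/AC next, TA better than reported. `predict(fit, fx$reads)` applies
the correction.

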