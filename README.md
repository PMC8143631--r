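# degronScreen

Chemical-proteomics screening for APC/C substrates, as a tested R pipeline.

## The problem

The anaphase-promoting complex/cyclosome (APC/C), with its G1 co-activator
Cdh1, degrades cell-cycle proteins that carry short degron motifs — D-boxes
(minimal `RxxL`, extended `RxxLxxxxN`) and KEN boxes (`KEN`) — in disordered
regions. A screen for APC/C^Cdh1 substrates arrests cells in G1, acutely
inhibits the APC/C, and quantifies the proteome with 10-plex TMT mass
spectrometry in biological triplicate: proteins stabilised under APC/C
inhibition that also carry a credible degron are candidate substrates.

`degronScreen` is aimed at proteomics analysts who want that analysis as
auditable, replayable code. It implements:

* **PSM-to-protein quantification** — column normalization of reporter
  signal-to-noise (S/N), exclusion of PSMs with summed S/N < 100, protein
  probabilities as the product of peptide posteriors, picked target–decoy
  protein FDR at 1%, maximum-parsimony protein inference (exact minimum set
  cover for ambiguity groups up to 12 proteins), and scaling each protein's
  channel vector to relative abundances (RA) summing to 100.
* **Differential statistics** — per-protein fold change (treated/control
  mean ratio), two-tailed unpaired pooled-variance Student's *t*-tests, a
  fold-change threshold calibrated as the median fold change of detected
  known substrates, the screen rule (fc ≥ threshold, >1 peptide,
  p < 0.05), a noncentral-*t* power analysis for the continuous per-group
  sample size at a 15% effect (α = 0.05, power 0.95), and a
  knockout-intersection rule (p < 0.05 and >20% change, direction-consistent
  in both clones).
* **Degron scanning** — exhaustive motif matching with 1-based inclusive
  coordinates, PWM similarity against a reference degron alignment,
  disorder and localization filters (similarity ≥ 0.75, consensus medium or
  high, disorder ≥ 0.4, intracellular and non-secreted), and Table-style
  candidate nomination grouped by D-box / KEN-box / both.
* **Mitotic-fraction statistic** — per-nucleus maximum-intensity
  distributions, empirical cumulative frequency curves, a control-derived
  intensity threshold, and the fraction of cells above threshold, plus
  optional image-based nucleus measurement (via `EBImage`).
* **Synthetic data with ground truth** — simulators for the TMT screen, a
  degron-bearing proteome and the nuclear-intensity assay, so every stage
  is testable against planted truth.

## Worked example

```r
library(degronScreen)

scr <- simulateScreen(seed = 11)   # 1000 proteins, 20 planted substrates
res <- runPipeline(list(
  psm = scr$psm, channels = scr$channels, proteome = scr$proteome,
  disorder = scr$disorder, localization = scr$localization,
  known_substrates = scr$knownSubstrates))

res$manifest$parameters$fc_threshold_used
#> [1] 1.148925
nrow(res$quant); nrow(res$screen); nrow(res$candidates)
#> [1] 986
#> [1] 47
#> [1] 20
head(res$candidates[, c("protein", "degron_group", "fc", "p",
                        "n_peptides", "best_d_similarity")])
#>   protein degron_group       fc            p n_peptides best_d_similarity
#> 1  P00747        D_box 2.665706 1.057435e-05          2              0.95
#> 2  P00039        D_box 2.476107 1.689318e-05          2              0.82
#> 3  P00686        D_box 1.685456 2.502831e-05          3              0.82
#> 4  P00696    D_and_KEN 2.850438 5.873040e-09          3              0.95
#> 5  P00478    D_and_KEN 2.768136 2.115254e-08          6              0.93
#> 6  P00213    D_and_KEN 2.741650 5.987693e-06          2              0.95
mean(scr$truth$substrates %in% res$candidates$protein)  # sensitivity
#> [1] 0.95
```

Reading the output: 986 of the 1000 simulated proteins survive picked FDR
and quantification; the nomination threshold calibrated on the simulated
known substrates lands at 1.149 (their true median fold change is 1.15);
47 proteins pass the screen rule and 20 also carry a passing degron, of
which 19 are planted substrates — 0.95 sensitivity at this seed. The run
manifest records every parameter actually used.

## Layout

```
R/                      implementation (simulators, quantification,
                        differential, degron scan, candidates, mitotic)
inst/extdata/           synthetic reference alignment + surrogate FASTA
tests/testthat/         unit, property and acceptance suites
scripts/acceptance.R    end-to-end reproduction script
vignettes/              methods vignette (models, parameters, limitations)
```
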