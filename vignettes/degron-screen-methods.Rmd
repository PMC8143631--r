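---
title: "Screening for APC/C substrates: methods and design notes"
author: "degronScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for APC/C substrates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronScreen)
```

## The scientific problem

The anaphase-promoting complex/cyclosome (APC/C) is the ubiquitin ligase
that clears cell-cycle regulators during mitotic exit and G1. Its
co-activator Cdh1 recognises substrates through short linear degron motifs
-- destruction boxes (minimal consensus `RxxL`, extended consensus
`RxxLxxxxN`) and KEN boxes (`KEN`) -- lying in disordered protein regions.
A chemical-proteomics screen for APC/C^Cdh1^ substrates arrests cells in
G1, acutely inhibits the APC/C with small molecules, and quantifies the
proteome by 10-plex TMT mass spectrometry in biological triplicate:
proteins stabilised under APC/C inhibition that also carry a credible
degron are nominated as candidate substrates. `degronScreen` implements
that analysis as a reusable, testable pipeline and pairs it with a
synthetic-data module so every stage can be validated against a known
ground truth.

## Quantification model

The quantitative readout is the TMT reporter signal-to-noise (S/N) of each
peptide-spectrum match (PSM) in each channel. The chain applied by
`quantifyProteins()` is:

1. **Identification.** Peptide posterior probabilities are multiplied (best
   posterior per distinct peptide, accumulated in log space) into a protein
   probability. Picked target-decoy FDR then keeps, for each target/decoy
   pair (paired by the `decoy_` identifier prefix), only the higher-scoring
   member, ranks survivors by score, computes the running FDR
   (#decoys / #targets at or above each cutoff), monotonizes it from the
   bottom into q-values, and accepts targets at q <= 1%. The protein
   probability is used as the picked-FDR score because it is the only
   protein-level score the procedure defines; note it penalises proteins
   with many peptides (a product of probabilities), which is tolerable for
   target/decoy separation but not a general-purpose protein score.
2. **Inference.** Candidate proteins are collapsed by maximum parsimony:
   ambiguity groups of up to 12 proteins are solved as exact minimum set
   cover (lexicographically smallest cover among minima), larger groups by
   the standard greedy cover. Shared peptides are then assigned razor-style
   to the retained protein covering the most peptides.
3. **Quantification.** PSMs with summed S/N below 100 are excluded (strict
   "less than"; the filter runs on the raw instrument scale before
   normalization by default, and the order is switchable). Channels are
   column-normalized so every channel total equals the mean of the raw
   totals. Finally each protein's channel vector is summed over its PSMs
   and scaled to sum to 100 -- the relative abundance (RA) convention.

### Compositional bias of the loading correction

Column normalization assumes equal loading, i.e. that the treatment leaves
the *total* protein mass per channel unchanged. When a noticeable share of
the proteome is regulated upward, the treated channel totals rise and
normalization compresses all fold changes by `1 / (1 + m (f - 1))`, where
`m` is the regulated mass share. With the study-like structure (a few
percent of proteins regulated) the bias is at the percent level and is
absorbed by calibrating the nomination threshold on known substrates --
precisely the role of that calibration. The parameter-recovery analyses
therefore measure the estimator on data whose loading is equal by
construction with `normalize = "none"`; a dedicated test asserts the
compression appears when the correction is applied to a heavily regulated
simulation. This is a property of the normalization convention, not a bug.

## Differential statistics

Per protein, the fold change is the ratio of treated to control RA means
and significance is a two-tailed, unpaired, pooled-variance Student's
t-test on the untransformed RA values (a log2 option exists; the default
mirrors the stated analysis). No multiple-testing correction enters the
screen decision -- the nomination rule uses raw p < 0.05 -- but a
Benjamini-Hochberg q-value column is emitted for reference. The screen
keeps proteins with fold change >= the calibrated threshold (boundary
inclusive), more than one distinct peptide, and p < 0.05 (strict).

The fold-change threshold is the median fold change of the known
substrates detected in the data (`calibrateFcThreshold()`); the run
manifest records the value actually used so its provenance is auditable.

The power analysis (`requiredN()`) solves the two-sample two-sided
noncentral-t power equation (via `power.t.test`) for a continuous number
of observations per group at effect size `d = (0.15 * mean) / sd`, with
significance 0.05 and power 0.95, bounded below by 2. The per-protein `sd`
is the pooled within-arm standard deviation of the RA values. At very
large effects the exact noncentral-t solution sits well above the normal
approximation `2 (z_0.975 + z_0.95)^2 / d^2` (at `d = 3`: 4.15 vs 2.89),
so tests pin it by Monte-Carlo power instead of the approximation.

The knockout-intersection rule (`koIntersection()`) calls a protein
decreased when p < 0.05 in both knockout-vs-wild-type comparisons with
fold change < 0.8 in both, and increased with p < 0.05 and fold change
> 1.2 in both -- "more than 20% change" read symmetrically on the linear
fold-change scale, not as a ratio interval.

## Degron scanning and filtering

`scanMotifs()` reports every occurrence (overlapping and nested included)
of `RxxL`, `RxxLxxxxN` and `KEN`, 1-based inclusive coordinates; a minimal
D-box nested at the start of an extended D-box is flagged, not removed.
The unknown residue `X` never satisfies an anchored position. An ABBA
class can be supplied as a custom pattern; no default consensus ships.

Similarity scoring builds a position-weight matrix from a reference degron
alignment (pseudocount 1, uniform 1/20 background) and min-max rescales
the hit's summed log-odds so the best reference sequence maps to 1 and the
worst possible sequence to 0, clamped to [0, 1]. The packaged reference
alignment is a small synthetic stand-in with correct anchor residues
(`degron_reference_synthetic.tsv`); scoring against the alignments used by
dedicated motif servers requires substituting those alignments, and
reproducing any particular server's numbers is out of scope. The
consensus-similarity category is derived from the same score (high >= 0.9,
medium >= 0.75, low otherwise) because no canonical category boundary is
published; both boundaries are arguments.

A hit passes (`filterHits()`) when similarity >= 0.75, consensus medium or
high, mean disorder over the span >= 0.4 (all inclusive), and the protein
is intracellular and non-secreted. Disorder is a per-residue input track;
`predictDisorder()` offers a crude window-averaged charge/hydropathy
heuristic as a fallback and is clearly not equivalent to curated
predictors. Proteins missing from the localization table are treated as
intracellular and non-secreted with a warning.

Candidates (`callCandidates()`) are the screen-passing proteins with at
least one passing degron hit, grouped as D-box / KEN-box / both (minimal
D-boxes count by default; `dMinEligible = FALSE` restricts eligibility to
the extended form), sorted by descending fold change within group. The
best-scoring passing hit per class supplies the reported scores
(`allHits = TRUE` reports all of them slash-separated).

## Mitotic-fraction statistic

In the fixed-cell assay, mitotic chromatin condensation makes the maximum
per-nucleus DNA-stain intensity much brighter than in interphase.
`cumulativeCurve()` computes the empirical CDF per condition;
`chooseThreshold()` derives the intensity cutoff from the control (DMSO)
wells -- by a control quantile, a fixed value, or a two-component split of
the log-intensity distribution -- and `mitoticFraction()` reports the
fraction of cells strictly above the cutoff, pooled across wells. The
mixture split is the default choice for recovery analyses because it needs
no prior knowledge of the control's mitotic share, mirroring the manual
practice of placing the cutoff where control mitotic cells separate from
interphase cells. `measureNuclei()` (optional, needs `EBImage`) segments
nuclei as connected components above a global Otsu threshold computed on
log intensity -- on the raw scale the threshold would split dim interphase
from bright mitotic nuclei instead of background from foreground -- and
reports each nucleus's maximum pixel value.

## What the simulators emulate -- and what they do not

`simulateTmt()` reproduces the *statistical* structure of the screen: a
10-plex with three biological replicates for control, treated and
time-zero arms plus one pooled bridge channel (time zero and bridge are
carried through quantification but excluded from the contrast); protein
abundances lognormal around a base S/N scale chosen so most PSMs clear the
summed-S/N 100 filter; about three peptides per protein (1 + Poisson(2));
multiplicative mean-one lognormal reporter noise with configurable CV
(default 0.10 -- the source data's per-protein CV distribution is not
published, so this is a free parameter, not an estimate); a configurable
minority of regulated proteins with fold changes drawn from [1.15, 3.6];
5% of peptides shared between two proteins to exercise parsimony; and 5%
decoy PSMs with low posteriors. A fixed seed makes outputs byte-identical.

`simulateProteome()` draws uniform-background sequences and plants degron
motifs (sampled from the packaged reference set) in regions whose
disorder track is >= 0.4. `simulateNuclei()` draws exactly
`round(fraction x n)` mitotic cells per condition from a brighter
lognormal intensity distribution (defaults: interphase meanlog log(1000),
sdlog 0.2; mitotic meanlog log(6000), sdlog 0.15 -- separable populations,
as in a working assay). `simulateScreen()` ties everything to one protein
namespace: by default 1000 proteins of which 20 novel substrates (fold
change 1.5-3, each with a planted extended D-box, half also a KEN box, and
at least two distinct peptides -- the nomination rule requires multi-peptide
quantification, so single-peptide substrates are unrecoverable by design),
38 "known" substrates whose true median fold change is 1.15 (so threshold
calibration can be rehearsed), 20 regulated degron-free proteins
(indirect effects) and 15 unregulated degron carriers (specificity
controls); the regulated mass is then a small share of the proteome, as
in the study design.

Not emulated: chromatographic fractionation, isotopic interference and
ratio compression, raw spectra, peptide-level identification errors
beyond the posterior/decoy mechanism, inter-plex batch structure, and any
biological correlation between pathways. Passing the recovery suites
therefore shows the *analysis* is correct and calibrated under the stated
noise model -- not that real instrument data meet that model.

## Numerical choices and degenerate inputs

* Zero pooled variance in the t-test raises an error distinct from p = 0;
  a channel with zero total S/N aborts normalization naming the channel;
  a posterior of exactly 0 yields protein probability 0 with a warning.
* Picked-FDR score ties rank decoys first (conservative); a tied
  target/decoy pair keeps the target.
* Parsimony tie-breaks are lexicographic at both the cover and the razor
  assignment level, making runs reproducible.
* `requiredN()` returns the lower bound 2 when the effect is so large
  that two observations per group already exceed the target power.
* The mitotic threshold is strict ("above"), so a threshold at or above
  the maximum yields fraction 0.
* All coordinates are 1-based inclusive; empty sequences yield empty hit
  tables; an empty PSM table makes `runPipeline()` warn and return an
  empty report rather than fail.

## Problem sizes used in the checks

The packaged checks run null calibration on ten screens of 2000 proteins
(type-I error within three binomial standard errors of 0.05),
fold-change recovery on >= 200 regulated proteins per planted effect in
{1.15, 1.5, 2.0, 3.6} at CV 0.05 (median within 5%), oracle equivalence on
500 random set-cover instances, 1000 random sequences and 200 random score
tables, end-to-end sensitivity/specificity over ten seeded 1000-protein
screens (sensitivity >= 0.9, false nominations <= 1%), and
mitotic-fraction recovery at n = 2000 nuclei per condition. These sizes
were chosen so the whole suite completes in a couple of minutes on one
CPU while leaving the binomial tolerances meaningful.

## Known limitations

* The similarity score is a PWM log-odds, not a re-implementation of any
  specific motif server's scoring; absolute similarity values are
  comparable only within one reference alignment.
* The packaged reference alignment and the IRS2-like worked-example
  sequence are synthetic surrogates (see file names); swap in real,
  licensed resources for production use.
* The protein-probability score makes picked FDR conservative for
  peptide-rich proteins.
* Column normalization is biased under large regulated mass (discussed
  above); consider `normalize = "none"` or a robust variant when the
  assumption fails.
* The built-in disorder heuristic is a coarse fallback only.
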