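---
title: "Windowed methylome analysis of oocytes, embryos and molar tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed methylome analysis of oocytes, embryos and molar tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methimprint)
```

## The problem

Human oocytes establish DNA methylation over transcribed gene bodies and at
the CpG islands of imprinted loci (maternal germline DMRs, gDMRs). When the
subcortical maternal complex is disrupted, oocytes show a genome-wide,
roughly multiplicative methylation deficit; conceptions form biparental
hydatidiform moles whose non-imprinted genome remethylates after
implantation while the gDMR deficit persists. Quantifying this requires
combining three very different data types — sparse depth-1 single-cell
bisulphite calls, deep bulk bisulphite libraries, and array beta values —
under one consistent quantification rule, and reasoning about maternal-allele
maintenance through the diploid dilution of the embryo.

`methimprint` implements that pipeline: windowed quantification with
coverage filters and an all-samples intersection, threshold-run domain
segmentation of reference germline methylomes, feature scoring of gDMRs and
CGIs, hypomethylated-region calling in molar array data, the
embryo-to-oocyte maintenance ratio, ZFP57 binding-motif methylation, and the
statistical tests mapped to each comparison.

## Quantification model and assumptions

Every methylation value is a *per-base-then-average* statistic: per-CpG
percentages are computed first and averaged unweighted within the window or
feature. This deliberately departs from count pooling — a deeply covered CpG
does not dominate its window — and for depth-1 single-cell data the two
coincide exactly (a property the test suite asserts). Missing windows stay
missing: no zero filling, and the grouped analyses use only windows covered
in *all* samples, reporting the retention fraction.

Coordinates are 0-based half-open for all intervals (BED convention) and
1-based for CpG positions (coverage-file convention); a CpG on a tile
boundary belongs to the window whose half-open interval contains its 0-based
position. CpG calls reported on the minus strand can be collapsed onto the
plus-strand C of the dyad (`collapse_strands()`), since CpG methylation is
quantified symmetrically and depth-1 data cannot resolve strands.

## Thresholds

All numeric cut-offs live in `default_config()`, each with a provenance
string. The inequality glyphs are part of the contract:

| parameter | value | role |
|---|---|---|
| tile widths | 50 kb (single cell), 20 kb (grouped, array), 10 kb (domains) | window quantification |
| site minima | 5 / 10 / 3 | observed CpGs (probes) per window |
| QC windows | 100 kb, step 10 kb | sliding per-cell profiles |
| domain rule | strictly > 70% or < 30%, >= 50 kb | run merging |
| CGI classes | strictly > 70% / < 20% | reference-methylome classes |
| hypomethylation | ratio strictly < 0.65, >= 10 CpGs | mole vs control placenta |
| maintenance | >= 20% residual oocyte methylation; 0.5 = perfect | embryo/oocyte ratio |
| ZFP57 | TGCCGC, GGCCGC | exact hexamer scan |

One boundary is genuinely ambiguous in the source analyses: whether a CGI at
exactly 70% counts as methylated. The package follows the strict reading
(`> 70` leaves 70% as intermediate) and keeps the threshold configurable
rather than silently choosing.

## The maintenance ratio

For feature *f* with germline methylation g_f and embryo methylation e_f,
the ratio r_f = e_f / g_f. Because the embryo is diploid and the paternal
allele is unmethylated at maternally methylated features, full maintenance
of the maternal allele yields r_f = 0.5; maintenance efficiency e scales
this to 0.5·e. Features with g_f < 20% are excluded — below that residual
level the ratio is noise-dominated. Ratios are computed per feature and
summarised by the class median (each feature counts once regardless of
size), and ratios above 1 are retained because post-fertilisation gains at
secondary DMRs are biologically real. For paternally methylated classes the
methylated germline (sperm) is the denominator; the contract is identical.
This denominator choice is implied rather than dictated by the analysis
design, so it is a documented default.

## Domain segmentation choices

Domain calling is a threshold-run algorithm, not an HMM: maximal runs of
*adjacent* qualifying 10-kb windows merge, and merged intervals under 50 kb
are discarded. Windows that are missing, intermediate, or separated by a
coordinate gap break runs — bridging across unobserved territory would
fabricate domain extent, so single sub-threshold windows inside long domains
split them (a documented behaviour, not a bug). Parental uniqueness uses the
strictest reading: a methylated domain is parent-unique only with zero
base-pair overlap against the other parent's methylated domains; a
majority-overlap mode is available for sensitivity analyses.

## Statistics

The test-to-comparison mapping is fixed: Wilcoxon signed-rank for paired
feature sets (domains, CGI classes, gDMRs, maintenance ratios), Student's
unpaired two-tailed t for per-cell statistics (global methylation, ZFP57
sites), Shapiro–Wilk only as an annotation, and for region-class effect
sizes a heteroscedasticity-robust omnibus (both Welch ANOVA and the
Brown–Forsythe F* with Satterthwaite denominator degrees of freedom)
followed by Dunnett-T3-style pairwise comparisons against the gDMR class.
The Brown–Forsythe means-ANOVA and the T3 adjustment are implemented in the
package: pairwise Welch t statistics with Satterthwaite degrees of freedom
and a Šidák-type studentized-maximum-modulus bound over the number of
comparisons (an independence approximation; with a single comparison it
reduces exactly to the Welch p). The Wilcoxon implementation switches from
the exact null distribution to the continuity-corrected normal approximation
at 25 informative pairs, since realistic feature-set sizes straddle that
range. Type-I error calibration of every test under its own null (n = 30,
1,000 seeded replicates, tolerance 2 points around the nominal 5%) is part
of the test suite.

## What the synthetic generator emulates

`sim_config()` defines the study conditions; the defaults are fixed and are
not tuned per analysis:

* **Genome** — the `"study"` preset builds two 1-Mb chromosomes with ten
  80-kb gene bodies on a 10-kb grid, 20 CGIs (half intragenic, half
  intergenic), six maternal gDMRs (mid-gene, CpG-dense, three planted ZFP57
  hexamers each), two paternal and two placenta-specific gDMRs in
  intergenic territory. Background CpGs every ~150 bp, island CpGs every
  ~15 bp — sizes chosen so domains comfortably exceed the 50-kb filter
  while the whole suite runs in seconds on one CPU. A `"tiny"` preset
  (one 0.5-Mb chromosome) serves the quick unit tests.
* **Oocyte** — gene-body CpGs methylated with probability 0.85, intergenic
  0.10, maternal/placenta gDMRs 0.85: coherent hypermethylated domains over
  transcription units, as in real oocytes.
* **Mutant oocyte** — per-region retention drawn once from a Beta law with
  mean `loss_factor` (default 0.55, in the range implied by an observed
  ~23%/37% global case/control contrast) and s.d. `loss_dispersion`
  (default 0.1), then fixed; methylation probabilities scale
  multiplicatively. Dispersion zero gives exact scaling, used by the
  parameter-recovery tests.
* **Sperm** — high globally (0.85), low at CGIs and maternal/placenta
  gDMRs, high (0.90) at paternal gDMRs. Under this model gene bodies are
  methylated in both germlines per-CpG, but called sperm domains break at
  the dense unmethylated islands, so parental-unique domain sets are
  non-empty at domain scale.
* **Single cells** — each CpG observed independently with probability 0.13
  (within the 11–15% per-cell coverage of saturated scBS-seq libraries) at
  depth 1, deterministically per (seed, track, cell index).
* **Embryo** — a whole-embryo bulk library: maternal allele = mutant-oocyte
  probability × `maintenance_efficiency`; paternal allele = sperm
  probability × `paternal_retention` (default 0.25, reflecting global
  post-fertilisation demethylation); counts drawn binomially with half the
  depth per allele (default depth 20).
* **Mole/placenta betas** — control placentas at an intermediate
  remethylation level (0.5) with low CGIs (0.10) and gDMRs at 0.5 (one
  methylated allele); the mole is identical except gDMR probes carry the
  oocyte-inherited retention on that single allele (beta = 0.5 × retention).
  Gaussian noise, s.d. 0.03, truncated to [0, 1]. The array's probe subset
  keeps all island/gDMR CpGs plus 30% of the background, mimicking the
  CGI bias of real arrays. No quantitative noise model exists for residual
  maintenance in molar tissue, so these two values are engineering choices.

Features real data have that the generator deliberately does not: spatial
autocorrelation of methylation within regions (CpGs are independent given
the regional probability), non-CpG methylation, bisulphite conversion
error, read-level structure, copy-number or cell-composition effects, and
array batch effects. Passing tests therefore demonstrate the correctness of
the window/domain/ratio logic under the stated sampling model, not
robustness to those artefacts.

## Numerical and degenerate-input choices

* Retention Beta draws use the mean/variance parameterisation; the variance
  is capped just below m(1 − m) so any requested dispersion stays proper.
* A window whose control methylation is exactly 0 while the mole is positive
  has an undefined ratio and is skipped with a warning; 0/0 counts as
  perfect retention (ratio 1).
* All differences zero in the paired test returns p = 1 with a degeneracy
  flag instead of erroring; zero-variance groups in the pairwise effect-size
  comparisons are flagged, never fabricated.
* Feature matching for gDMR controls (methylation within ±5 points, CpG
  density within ±20%, 10 matches per gDMR) uses defaults that are exposed
  as arguments because the underlying procedure is under-specified; they are
  choices of this package, not claims.
* Random 50-CpG windows for the variability baseline span exactly 50
  consecutive CpGs of the control calls' CpG universe.
* Derived RNG seeds (per cell, per stage) are combined additively modulo
  2^31 − 1 and restored after use, so generation is reproducible per
  component and independent of call order.

## Problem sizes

The shipped tests run the full stack at the study preset (two 1-Mb
chromosomes, ~30,000 CpGs, 5 cells per genotype, depth-20 references and
embryo, 11 control placentas) and the statistical calibration at 1,000
replicates — a deliberate desk-scale choice that keeps the whole suite
around a minute while leaving every estimator's Monte-Carlo error well
inside the asserted tolerances. Real-study scale (160k+ genome windows,
hundreds of thousands of array probes) differs only in size, not code path.

## Known limitations

Allele-resolved maintenance is out of reach without phasing; repeat-element
methylation via consensus mapping, array preprocessing/normalisation,
liftover and alignment upstream of the call tables are out of scope. The
analysable-window count of an array run depends on the probe manifest, so
absolute window counts are not comparable across platforms.
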