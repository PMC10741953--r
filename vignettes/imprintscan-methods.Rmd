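---
title: "imprintscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{imprintscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## Scope and model

`imprintscan` addresses a recurring design in epigenetic disease modelling:
a panel of control samples, a small number of patient samples, and
mutation-corrected clones derived from the patients, all profiled on
methylation arrays. The question has three layers — where does a patient
deviate from the control panel, do those deviations organise into wider
genomic domains, and does correcting the causal mutation return the
epigenome to the control state? Imprinted differentially methylated
regions (iDMRs) get dedicated treatment because their expected methylation
(≈50% in somatic tissue, frequently hypermethylated in pluripotent cells)
and their biological stakes differ from the genomic background.

### The calling statistic

For every unit (CpG, 500 bp bin average, or region average) the control
panel defines a reference: mean and standard deviation of control M-values
(sample SD, n − 1), and the median control β. A test sample is called
differentially methylated when, jointly and strictly,

$$ |\Delta M| > k \cdot \mathrm{SD}(M_{\mathrm{ctrl}}), \qquad
   |\Delta\beta| > \delta, $$

with defaults k = 3 and δ = 0.2, hyper when Δβ > δ, hypo when Δβ < −δ.
The two criteria play different roles: the M-scale z-like criterion adapts
to per-unit control variability (M-values are closer to homoscedastic than
β near the scale ends), while the β-scale criterion enforces a biologically
meaningful minimum effect size regardless of how quiet the controls are.
ΔM is referenced to the control **mean** and Δβ to the control **median**.
This asymmetry is kept deliberately: it is how the procedure the package
reimplements was defined, the median making the effect-size criterion
robust to a single aberrant control while the mean/SD pair retains the
usual z-statistic interpretation.

Degenerate references with SD(M) = 0 (identical controls, essentially only
in constructed data) make the first criterion vacuous; such units are
called on the β criterion alone, counted, and flagged with a warning
rather than silently passed or dropped.

### Conversions and clipping

M = log2(β/(1 − β)) after clipping β into [ε, 1 − ε], ε = 0.001
(configurable, validated to lie in (0, 0.5)). Arrays do produce β of
exactly 0 or 1; clipping caps |M| at ≈9.96 and distorts nothing else. The
inverse transform is exact on the clipped range (round-trip tested to
1e−9), and the transform is antisymmetric — β → 1 − β maps M → −M — which
yields the mirror-symmetry property used in the tests: complementing every
β swaps hyper and hypo labels exactly.

### Filters

Probes are removed, with one attributed reason each (detection → SNP → sex
→ missing), when: detection p > 0.01 in *any* sample (the strictest common
per-sample rule; the source procedure cites its toolkit's defaults without
spelling one out, so the rule is explicit and configurable here); the
manifest flags SNP overlap or a sex chromosome; or the β value is missing
in any sample. A second, control-consistency filter removes units where
any single control deviates from the control *mean* β by more than 0.2 —
this guards the reference itself against lines with idiosyncratic
methylation (a documented phenomenon at imprinted loci in reprogrammed
cells). Whether this filter ran before or after batch correction in the
original procedure is unstated; the package applies it to whatever matrix
it is given and leaves upstream normalisation out of scope.

### Bins, clusters, regions

The genome is tiled into 500 bp bins anchored at coordinate 0 of each
chromosome (the anchoring phase is a convention; 0 is reproducible and
assumption-free). Bins need ≥ 2 CpGs; their per-sample value is the
unweighted probe mean, and a sample with any missing member yields a
missing bin value (per-sample completeness — the stricter of the two
readings of "at least 2 CpGs", flagged for sensitivity analysis). Bin
calling rebuilds a *bin-level* reference from the bin β-averages rather
than aggregating probe-level calls, so a bin is judged by the same
statistic as a CpG. Clusters are maximal runs of dm bins whose starts
differ by exactly 500 on one chromosome; a bin separated by an excluded
low-coverage bin is *not* contiguous (a literal reading of contiguity —
the gap tolerance is a parameter, defaulting to none). Region analysis
(iDMRs) is the same machinery with ≥ 3 probes per region.

### iDMR grouping and recovery

Regions are grouped by mean control β: high ≥ 0.60, intermediate
[0.40, 0.60), low < 0.40. The anchors (60% and 40%) come from the
reference analysis's three-group description; that description leaves
(50%, 60%] and exactly 40% unassigned, and the package closes the gaps
with the minimal total partition above rather than leaving regions
unclassifiable. A unit dm in a patient is *recovered* in a corrected
clone when |β_clone − median(β_controls)| < 0.2, strictly; the summary
reports per-clone percentages, optional per-class breakdowns (classes
with no calls are omitted), and the count of units dm in *every* patient
that recovered in *every* clone of both patients.

### Enrichment and overlap statistics

ChIP fold change is FC = (IP count/IP depth)/(input count/input depth);
zero input counts get a 0.5 pseudocount added to both counts of that
record and a flag (avoiding infinities while preserving order — this
breaks exact scale invariance only on flagged records). Condition
comparisons use the paired one-sided Wilcoxon signed-rank test (exact
when tie- and zero-free, tie-corrected normal approximation otherwise;
zero differences dropped by the standard convention), BH-FDR within the
family of comparisons requested in one call, and the paired rank-biserial
r = (W⁺ − W⁻)/(W⁺ + W⁻). The one-sided direction must be stated by the
caller; the package does not guess it. Δβ distributions are compared with
the two-sided two-sample Wilcoxon test. The overlap of two dm-unit sets
is assessed by a seeded shuffle test: redraw |A| units uniformly without
replacement from the analysed universe, count overlaps with B, and report
p = (b + 1)/(n_perm + 1). The universe is the post-filter unit set; the
granularity (CpGs, bins or regions) is the caller's choice, since the
reference analysis does not state its shuffle scheme. The p-value floor
is 1/(n_perm + 1) by construction, so "p < 10⁻⁶" claims require ≥ 10⁶
permutations.

## The synthetic world

`simulation_config()` states the emulated design once; its defaults are
the study design the package mirrors, not tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_controls` | 11 | the emulated control-panel size |
| `n_patients`, `clones_per_patient` | 2, 2 | two patients, two corrected clones each |
| `planted_effect` | 0.4 | severe iDMR hypomethylation is a Δβ of this order |
| `control_noise_sd` | 0.02 | inter-control β spread of a clean array panel |
| `planted_hypo_fraction` | 0.2 | of eligible (high-β) bins and iDMRs planted hypo |
| `shared_fraction` | 0.7 | dm loci shared by both patients (≈ the 70–80% concordance the emulated study reports) |
| `resistant_fraction` | 0.25 | planted loci that do not recover in clones (bin recovery 71–92% in the emulated study) |
| `fibroblast_idmr_level` | 0.5 | somatic iDMRs sit near 50% methylation |
| `chip_fc_at_hypo` | 3.0 | H3K4me3-like IP/input enrichment at hypo iDMRs |
| `unstable_control_fraction` | 0.05 | iDMRs given one outlier control, to exercise the consistency filter |

Background CpGs sit two per 500 bp bin; per-bin baselines are bimodal
(low mode ≈0.10, high ≈0.88) with small per-probe jitter, so the β
distribution has the familiar array two-hump shape. iDMR probes tile the
bundled 50-region fixture at 100 bp; region baselines follow the group
levels (high 0.80–0.92, intermediate 0.45–0.55, low 0.15–0.35) with group
membership drawn from `idmr_group_fractions` (0.5/0.3/0.2 — the high
group is the largest, the low group the smallest, as in the emulated
panel). Noise is additive truncated Gaussian on the β scale: array noise
is approximately β-homoscedastic at mid-range, and planted effects are
specified on the β scale, so a β-scale noise model keeps truth arithmetic
exact. Planted hypomethylation is carved into runs of lengths cycling
3, 2, 1, 2, 1 within stretches of high-baseline bins, with at least one
unplanted bin between runs — so planted ≥2-bin runs are exactly the
maximal dm runs a correct cluster detector should find, and 1-bin
plantings are exactly the isolated bins. Corrected clones redraw
non-resistant planted loci from the control distribution and keep
resistant loci at patient level. ChIP counts are Poisson with IP rate
multiplied by `chip_fc_at_hypo` at planted iDMRs in patients, persisting
only at resistant iDMRs in corrected samples.

What the generator does **not** emulate: probe-type chemistry effects,
batch structure, spatially varying noise, allele-specific signal, and any
realistic linkage between CpG density and methylation. A green end-to-end
test therefore establishes that the pipeline recovers *planted* structure
under idealised noise — it says nothing about normalisation or batch
robustness, which are upstream of this package by design.

Fibroblast control samples carry role `control` with cell type
`fibroblast`; reference construction and the consistency filter default to
the iPSC control panel (`cell_type = "iPSC"`) so somatic samples inform
comparisons without contaminating the panel.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere; a probe at a region start
  is inside, at the end is not. No "chr" normalisation is applied —
  silent renaming hides input errors.
- Missing β is `NA`, never 0; 0 is a legal methylation value.
- All inequalities in calling and recovery are strict, matching the
  "larger than" wording of the reimplemented procedure.
- Removal reasons in the filter report are attributed in a fixed order so
  reports are deterministic.
- The region-filter attribute `n_probes` documents input coverage; the
  filter is idempotent and preserves input order.
- Randomness (shuffle test, generator) runs under a locally seeded RNG
  that restores the caller's RNG state.
- The bundled iDMR catalogue is *synthetic*: real locus names, fabricated
  coordinates, frozen so that 42 of 50 regions carry ≥ 3 probes under the
  generator's probe spacing. The live upstream catalogue is versionless
  and treated as external input.

## Known limitations

- No smoothing-based DMR detection; clusters are exact-run unions of
  fixed-phase bins, so a dm domain straddling a bin boundary with a
  low-coverage bin in the middle is reported as two clusters.
- Per-sample bin completeness (a bin is `NA` for a sample missing any
  member probe) is stricter than a per-panel rule; with array-scale
  missingness this discards some callable bins.
- The paired Wilcoxon falls back to a normal approximation in the
  presence of ties or zeros; exactness is only guaranteed on tie-free
  data (the regime the exactness tests cover).
- The pipeline consumes *normalized* β matrices; IDAT import,
  normalisation, batch correction and coordinate lift-over are explicitly
  out of scope.
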