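---
title: "Dual-isotope qSIP: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope qSIP: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsip)
```

## The measurement model

DNA-SIP incubates a community with an isotopically labelled substrate;
organisms that assimilate it build heavy isotopes into their DNA, which
then reaches buoyant equilibrium deeper in a CsCl gradient. After
ultracentrifugation the gradient is cut into fractions (13 in the design
this package targets), each fraction's density is read by refractometry,
its total 16S rRNA gene copies are measured by qPCR, and its community
composition by amplicon sequencing. The per-fraction data for one
incubation form a `gradient_profile`; an experiment is a pair of profiles —
unlabelled control and labelled treatment — sharing a substrate.

Per OTU, the estimator chain is:

1. **Copy numbers.** Reads are normalised to relative abundance per
   fraction-sample and multiplied by the fraction's qPCR total. Only ratios
   within a fraction matter downstream, so sequencing depth cancels; the
   qPCR totals carry the quantitative weight.
2. **Weighted average density (WAD)** in each treatment: the copy-weighted
   mean of fraction densities. It is scale-invariant in the copy vector and
   bounded by the observed density range.
3. **GC content** from the unlabelled WAD via
   $G = (W_{light} - 1.646057)/0.083506$. Estimates outside $[0,1]$ are
   clamped with a warning (the choice to clamp is this package's; values
   beyond the bounds can only arise from noise).
4. **Molecular weights.** $M_{LIGHT} = 0.496\,G + 307.691$;
   $M_{LAB} = (\Delta W / W_{light} + 1)\,M_{LIGHT}$, using the
   proportionality of buoyant density to molecular weight.
5. **Maximum heavy weight and MWE.** Under full ¹³C + ¹⁵N substitution,
   $M_{HEAVYMAX} = 0.0025\,G + 13.416 + M_{LIGHT}$, and
   $MWE = (M_{LAB} - M_{LIGHT})/(M_{HEAVYMAX} - M_{LIGHT})$.
6. **Activity call**: $MWE \ge 0.14$, inclusive.

### Why MWE rather than atom fraction excess

With a single isotope, the density shift maps one-to-one to an atom
fraction excess (AFE). With two isotopes assimilated simultaneously, one
observed shift reflects two unknown enrichments; only their combined mass
effect is identifiable. MWE expresses that combined effect on a 0–1 scale
where 1 means every carbon and nitrogen atom replaced. AFE is therefore
deliberately not computed in the dual-isotope path; setting
`isotopes = "C"` in `qsip()` restores classic carbon-only behaviour (the
maximum increment becomes $9.974564 - 0.4987282\,G$), which is also how the
dual-isotope machinery reduces to the single-isotope special case in tests.

### The two conventions for the dual maximum

The combined relation $0.0025\,G + 13.416$ is used verbatim by the default
analysis path (`max_heavy_mode = "printed"`). Summing the carbon term and
the GC-weighted mean of the per-base ¹⁵N gains (A, G: 4.985; T: 1.994;
C: 2.991 g mol⁻¹) instead gives $13.464 - 0.0002\,G$ — close, but not the
same line. The provenance of the combined coefficients cannot be
reconstructed from the per-base masses, so both conventions are exposed
(`max_heavy_mode = "per_element"`) rather than silently reconciling them.
At realistic MWE values the difference is below 0.4% of the estimate.

### No natural-abundance correction, no bootstrap by default

Natural isotope fractions are present identically in both treatments and
cancel in the density comparison, so no correction is applied. Uncertainty
quantification by resampling is off by default — the target design has one
replicate per condition, which is exactly why the stringent fixed cutoff
exists. `qsip_bootstrap()` offers a fraction-resampling bootstrap as a
labelled extension for gauging estimator spread; with only ~4 informative
fractions per band its intervals are wide, and it is no substitute for
biological replication.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `threshold` | 0.14 | – | inclusive MWE cutoff for activity; stringent, suited to unreplicated designs |
| `isotopes` | `"CN"` | – | dual or carbon-only maximum |
| `max_heavy_mode` | `"printed"` | – | combined vs per-element dual maximum |
| `min_total` | 13 | reads | per-incubation OTU minimum (strictly fewer are dropped): one read per fraction of a 13-fraction gradient |
| `taxa_to_drop` | Cyanobacteria | – | lineages indistinguishable from substrate-carryover DNA |
| `band_sigma` | 0.006 | g ml⁻¹ | Gaussian band width; spans ~3–4 of 13 fractions |
| `qpcr_cv` | 0.10 | – | lognormal CV of simulated qPCR totals, a typical replicate spread |
| `density_range` | 1.660–1.780 | g ml⁻¹ | simulated gradient span, centred near a 1.725 loading density |

The minimum-count rule is interpreted as a *total over the incubation's
fraction-samples*: a per-fraction minimum of 13 would remove nearly every
OTU, whereas the total ties naturally to the 13-fraction design. It is
applied per incubation, so an OTU may be analysed for one substrate and not
another; within a pair, eligibility additionally requires nonzero copies in
both members (exclusions are recorded with reasons, never fatal). The
default filter order (singletons where applicable → minimum count →
taxon removal) is logged; the filters are monotone, so no order can
resurrect a removed OTU, only the surviving set differs at the margin.

## What the simulator emulates — and what it does not

`simulate_gradient_pair()` forward-models the chain the estimator inverts:
Gaussian bands in density (centre set by GC and, in the labelled member, by
true MWE through the same proportionality the estimator uses), band mass
integrated over equal-width fraction bins via the Gaussian CDF (the
outermost bins absorb the tails so mass is conserved exactly), multinomial
read sampling at finite depth, and lognormal multiplicative qPCR noise.
A single integer seed makes every run reproducible, and an `analytic` mode
stores exact expected copy masses so the pipeline can be tested as an exact
inverse of the forward model.

Real gradients add effects the simulator deliberately omits: PCR
amplification bias and chimeras, 16S copy-number variation between taxa,
non-Gaussian or compressed bands, density drift between runs, and DNA
losses during fraction precipitation. Passing the recovery tests therefore
demonstrates the estimator is a correct and well-conditioned inverse of the
stated physical model at realistic noise — not that field data meet that
model.

## Numerical choices and degenerate inputs

* Band integration uses CDF differences per bin, not midpoint sampling;
  with 13 fractions the residual discretisation error in a WAD is below
  $5\times10^{-4}$ g ml⁻¹ provided bands sit a few σ inside the gradient.
  The validation grid that includes fully labelled high-GC DNA (band centre
  ≈1.779 g ml⁻¹) therefore spans 1.64–1.80 g ml⁻¹, so every band sits
  ≥3.5σ inside the fractionated range; the default span is kept at
  1.660–1.780 for realism.
* All-zero copy vectors make a WAD undefined: an error at the operation
  level, a recorded exclusion at the fit level.
* GC clamping tolerates floating-point roundoff (1e-9) before warning.
* Densities outside 1.55–1.85 g ml⁻¹, negative counts, duplicate OTU or
  fraction ids, and profiles with fewer than three positive-copy fractions
  are rejected at construction, with messages naming the offending column,
  line or id.
* Results are written at full double precision and round-trip through the
  reader to better than 1e-9.

## Validation summary

The test suite establishes, at the sizes noted (chosen to exercise the
statistics while keeping the default run fast):

* exact agreement of all constants and the maximum-labelling equation with
  their closed forms;
* noiseless inversion: 200 OTUs on a GC ∈ [0.3, 0.7] ×
  MWE ∈ {0, 0.05, 0.14, 0.3, 0.5, 1} grid recover true MWE within 1e-3;
* noisy recovery: at 13 fractions, 10⁵ reads/sample, qPCR CV 0.10,
  3 seeds × 200 OTUs, |bias| < 0.02 and ≥95% classification accuracy for
  true MWE at least 0.05 from the cutoff (observed: |bias| ≤ 0.002,
  accuracy 100%);
* invariant sweeps (WAD bounds and scale invariance, MWE monotonicity,
  density↔GC inverse identity to 1e-12, filter monotonicity, abundance
  column sums, activity-table percentages, copy-partition additivity);
* the community-level signature: with a minority of heavily labelled OTUs,
  the copy-weighted density of the active community exceeds the all-OTU
  mean in every tested replicate.

## Known limitations

MWE confounds the two isotopes' enrichments by construction; the cutoff is
a judgement call, not a significance test; absolute per-litre abundances
inherit the uncertainty of DNA extraction yields and are flagged as
estimates; and taxa whose bands fall partly outside the fractionated
density range are biased toward the gradient interior — visible in the
simulator when `density_range` is set too narrow for heavily labelled
high-GC taxa.
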