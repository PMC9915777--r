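---
title: "Prioritizing VUSs by predicted folding destabilization: methods"
author: "vusfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing VUSs by predicted folding destabilization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vusfold)
```

## The problem and the model

A missense variant can be pathogenic through many mechanisms; the one
this package targets is loss of the folded state. Writing the folding
free energy difference as ΔΔG = ΔG_fold(variant) − ΔG_fold(wild type)
(kcal/mol, positive = destabilizing), the equilibrium constant between
folded and unfolded states is multiplied by exp(−ΔΔG/RT). Requiring an
r-fold *decrease* of the folded:unfolded ratio inverts to the threshold

ΔΔG* = RT·ln r.

For r = 20 and R = 1.98720425×10⁻³ kcal/(mol·K):

```{r thermo}
round(ddg_threshold_for_fold_change(20), 3)          # 298.15 K
round(ddg_threshold_for_fold_change(
  20, thermo_params(temperature = 310.15)), 3)       # body temperature
```

Both round to 1.8 kcal/mol. The one-decimal threshold is insensitive to
the temperature convention across approximately 294–310.8 K; below or
above that range the rounding tips to 1.7 or 1.9, so the package
defaults to 298.15 K and exposes the temperature as a parameter rather
than hard-coding either convention.

The working hypothesis is that a variant at or beyond this threshold
loses enough folded population for loss of function and likely
degradation — a *sufficient* mechanism, not a necessary one, which is
why sensitivity against all pathogenic variants is intentionally low.

ΔΔG values are *inputs* to this package (they come from upstream
structure-based predictors); nothing here recomputes them.

## Threshold calibration

Labeled variants calibrate how trustworthy a threshold call is. The
calibration set uses **positives = P, negatives = B** only: the
likely-* tiers are themselves model-inferred and would contaminate the
positive class, and only the P/B convention is consistent with the
joint-rule operating point the pipeline is built around (793 true
positives against 8 false positives among 1,725 benign variants gives
PPV = 793/801 = 99.0% and specificity 99.5%, the internal-consistency
reconstruction shipped in the tests). Both labels are arguments, so the
convention is overridable.

Decision rules use **strict inequalities** (`ΔΔG > t`, `CADD > c`);
equality is a negative call. Records missing a required score are
excluded from calibration and counted, never silently treated as
negative — 0 kcal/mol is a meaningful value ("neutral"), so missingness
must stay distinct from zero.

`find_cadd_threshold()` searches the **observed CADD values** (sorted,
distinct) for the smallest threshold whose joint-rule PPV reaches the
target. An observed-value grid guarantees the minimal achieving
threshold is representable exactly; a fixed-step lattice could only
bracket it. The search is verified in the tests against an independent
brute-force scan of the full grid, and an unachievable target is a loud
error carrying the best attainable PPV.

The mirror-image rule for **over-stabilizing** variants
(ΔΔG < −|t|) is implemented behind the same interface via the
`direction` flag, but default prioritization uses the destabilizing
direction only: over-stabilization is rarer and calibrates to a
noticeably worse PPV, so it is exposed for analysis rather than wired
into the default upgrade path.

## Structural features

Per-residue confidence (pLDDT, 0–100) is read from the PDB
temperature-factor column of the residue's **CA atom**; structure
predictors write one value per residue on every atom, and CA exists in
every complete residue, so the CA value is the residue value without
averaging artifacts. Confidence is binned into `<50`, `50-70`, `70-90`,
`>90`, left-closed and half-open with the top bin closed at 100, so the
four bins partition [0, 100] exactly: 50 falls in `50-70`, 90 in `>90`.
The high/low-confidence split used in grouped statistics is at 70.

Solvent accessibility uses the Shrake–Rupley algorithm: each atom's van
der Waals sphere is inflated by the probe radius (default **1.4 Å**, a
water molecule) and sampled with a deterministic golden-spiral lattice
(default **960 points**; doubling changes the toy-helix answer by under
2%, and the tests pin agreement with an independent implementation to
within 5% per residue). Relative SASA divides the residue sum by the
Tien et al. (2013) *theoretical* maximum ASA for the residue type;
values above 100% occur for highly exposed residues and are reported
unclamped. Residue types outside the twenty standard amino acids get an
absolute but no relative value.

## Prioritization, summaries, extrapolation

`select_priority_vus()` applies the calibrated joint rule to VUS-labeled
records only. Per-gene summaries report prioritized VUSs per 1000 amino
acids; the inclusion cut (default density ≥ 30) is applied to the
*unrounded* density, and densities and mean scores are rounded to one
decimal for reporting, with means taken over unrounded inputs.

The hidden-pathogenic extrapolation assumes the prioritized VUSs are the
misfolding-driven fraction f of all pathogenic variants still hidden
among VUSs, where f is measured on known pathogenic variants at the same
thresholds. The default rounds f to one decimal of a percentage before
dividing (f = 793/6328 → 12.5%), which is the convention under which the
headline count of 24,192 non-misfolding hidden pathogenic variants is
exactly reproducible; the unrounded estimate (≈ 24,122) is always
reported alongside:

```{r extrap}
res <- estimate_hidden_pathogenic(6328, 793, 3456)
res$estimated_non_misfolding_pathogenic
round(res$estimated_non_misfolding_pathogenic_unrounded)
```

Between-class location differences in `class_statistics()` are tested
with a two-sided Mann–Whitney (Wilcoxon rank-sum) test; the package
reports its own p-values and does not attempt to reproduce any
externally printed ones, whose test statistic is unspecified.

## Diagnostic logic

An upgraded (prioritized) VUS yields a **definitive** diagnosis for an
autosomal dominant case on its own, and for an autosomal recessive case
when the proband's second variant is classified P or LP and segregation
does not refute a trans configuration. Segregation that was simply not
performed (`unavailable`) does **not** block the diagnosis — it flags
the outcome `unconfirmed` — because the clinical practice the rule
mirrors issues diagnoses in that situation; refuted segregation forces
`inconclusive`. An AR case carrying a second variant without a
classification is rejected as invalid input rather than guessed at.

## What the synthetic generator emulates — and what it does not

`generate_variant_table()` draws, per variant: a class from the
five-tier proportions (defaults: the published class-by-confidence
counts normalized, ≈ B 1.3%, LB 21.8%, VUS 70.0%, LP 1.9%, P 4.9%); a
confidence bin from the class's stratum probabilities and a uniform
value within the bin; and (ΔΔG, CADD) from a Gaussian copula
(default correlation 0.5) with class-conditional marginals, ΔΔG replaced
by exactly 0 with the class's neutral point-mass probability.

The defaults were fixed once, before any end-to-end runs, as follows.
The B and P ΔΔG means (0.13 and 0.80 kcal/mol) are the published class
means. No distributional family, spread, or neutral share is published
per class, so the remaining parameters are the simplest shape matching
the reported aggregate structure: Gaussian marginals plus a zero atom of
0.14 in every class, standard deviations B/LB 0.8, VUS 0.9, LP 1.1,
P 1.2, and interpolated means LB 0.13, VUS 0.45, LP 0.70 — chosen so the
overall mixture lands near the published 59% destabilizing / 27%
stabilizing / 14% neutral split and so that roughly 17% of P variants
exceed 1.8 kcal/mol, as reported for the real catalogue. CADD marginals
(B/LB 15±4, VUS 20±5, LP 26±4, P 27±4) are generator inventions with no
published counterpart, picked only to place the calibrated cutoff in a
plausible low-to-mid-20s range. Relative SASA is Beta-distributed with a
burial bias for P/LP; MAF is log-uniform on 10⁻⁶–10⁻²; domain membership
is Bernoulli with higher probability for P/LP.

The generator does **not** emulate: per-gene length or mutation-rate
structure (genes are assigned round-robin from a configurable list),
LD or recurrence between variants, the heavy non-Gaussian tails of real
ΔΔG predictors, annotation missingness patterns, or any relationship
between sequence context and scores. Passing recovery tests on this
generator therefore demonstrates that the *machinery* (calibration
search, selection, summaries, diagnosis) is correct under the stated
statistical structure — not that the thresholds would attain the same
operating characteristics on a new real catalogue.

## Problem sizes and determinism

The test suite and acceptance script use 50,000-variant synthetic tables
(a desk-scale stand-in for the ~128,000-variant catalogue), 20-residue
toy helices and a 27-residue packed cluster for structural features, and
the six-proband transcribed case table. Every stochastic stage takes an
explicit seed; toy-structure geometry is fully deterministic. At these
sizes the entire suite runs in a few seconds.

## Known limitations

* ΔΔG predictions are consumed at face value; their ~1–1.5 kcal/mol
  typical error is not propagated into the calls.
* The pipeline tests only the misfolding hypothesis; pathogenic variants
  acting through active sites, interfaces, splicing or dosage are
  invisible to it, which the extrapolation step quantifies rather than
  fixes.
* Thresholds are proteome-wide; proteins intolerant of small
  destabilizations (or domains with localized sensitivity) would need
  per-gene or per-domain calibration, which the API permits (filter the
  table, recalibrate) but does not automate.
* Relative SASA depends on the chosen maximum-ASA scale; the shipped
  Tien et al. theoretical table is one defensible convention among
  several.
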