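---
title: "Twin-ion mass-shift filtering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-ion mass-shift filtering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoshift)
```

## The method

A drug candidate is incubated twice under identical conditions — once as a
stable-isotope labeled form (here deuterium: d4 pioglitazone, d3
flurbiprofen), once un-labeled — and each reaction mixture is measured by
LC-MS in a separate run. Any metabolite that retains the labeled positions
is present in both mixtures at nearly equal abundance, so its ion must
appear in both runs as a *twin ion* pair separated by exactly the label
mass. Filtering aligned feature lists for such pairs detects metabolites
without assuming anything about the metabolic chemistry, which is what
defeats list-based and defect-based screens.

A pair of features $(u, l)$, $u$ from the un-labeled run and $l$ from the
labeled run, is kept when all three conditions hold (all bounds inclusive):

1. **Mass shift.** $|\,(m/z_l - m/z_u) - \Delta\,| \le \delta_m$, with
   $\Delta$ the nominal label shift and $\delta_m$ the shift tolerance.
2. **Co-elution.** $|\,rt_l - rt_u\,| \le \delta_{rt}$.
3. **Intensity similarity.**
   $|\,(I_l - I_u)/I_u\,| \le \delta_I$ evaluated on base-peak-relative
   intensities $I = 100\,i/\max_\text{run}(i)$.

### Assumptions

* Singly charged ions ($[M+H]^+$ or $[M-H]^-$); the label is retained
  through metabolism (loss of the labeled site is checked separately by
  re-filtering at partial shifts).
* The two runs share one LC gradient, so a constant retention-time
  tolerance suffices (no warping).
* The chromatographic deuterium effect makes the labeled form elute
  *earlier* (one-sided), and differential ion suppression perturbs its
  intensity multiplicatively.

## Parameters

| parameter | units | default | why |
|---|---|---|---|
| `mass_shift` | amu | per label (4.00 d4, 3.00 d3) | nominal filter center; the exact d4 shift is $4(m_D - m_H) = 4.0251$, inside the 0.04 window |
| `mass_tol` | amu | 0.04 (d4), 0.03 (d3) | TOF mass accuracy; widening to 0.5 emulates unit-resolution instruments |
| `rt_tol` | min | 0.1 | envelope of the observed deuterium retention shift |
| `intensity_drift` | fraction | 0.5 | envelope of differential ion suppression between labeled/un-labeled forms |
| co-elution `rt_window` | min | 0.05 | half the rt tolerance; groups in-source fragments, which share the apex exactly |
| formula `ppm_tol` | ppm | 5 | TOF accurate-mass tolerance |
| element bounds | counts | C40 H60 N8 O15 S3 F3 | covers drug-like ions below m/z 1000; F is opt-in by the user, never auto-detected |
| `rdbe_min` |  | −0.5 | conventional floor for even-electron ions |
| loss/transformation `tol` | amu | 0.01 | accurate-mass match window |
| defect `half_width` | mDa | 40 | conventional defect-filter window |

The intensity criterion uses *relative* intensities by default because
published pair tables report base-peak-relative percentages and because
this makes the test invariant to global signal-scale differences between
runs; `intensity_mode = "raw"` is available. With `require_intensity =
FALSE` the criterion can be switched off to study how much background it
suppresses.

## Numerical choices

* **Masses.** CODATA/IUPAC monoisotopic masses to at least 7 significant
  decimals (C exactly 12, H 1.00782503207, D 2.01410177785, ...);
  electron mass 5.48580e-4 amu is subtracted (cations) or added (anions)
  when converting an ion formula to m/z. These reproduce every
  internally consistent published formula mass to ≤ 1e-5 amu.
* **Mass defect.** `frac(x) = x − trunc(x)` (truncation toward zero; all
  masses here are positive), defect in mDa =
  `(frac(metabolite) − frac(parent)) × 1000`.
* **Inclusive windows.** Every "±" tolerance in the package is an
  inclusive bound (`<=`), uniformly, so boundary cases behave identically
  in the filter, the subtraction step, the baselines and the detector.
* **One-to-one conflict resolution.** When a feature passes the criteria
  against several partners, candidates are accepted greedily by ascending
  normalized distance
  $d = |\Delta_{mz} - \Delta|/\delta_m + |\Delta_{rt}|/\delta_{rt}$ with
  deterministic tie-breaks (lower labeled m/z, then lower un-labeled m/z,
  then earlier rt). The originating study does not state its rule; this
  one is reproducible and is property-tested against a brute-force
  enumeration with the same resolution on hundreds of random maps.
* **Mixture mode.** When labeled and un-labeled material is measured in a
  single run, pairs are formed within one map and the lighter member is
  reported as un-labeled — correct whenever the label is retained, since
  the labeled ion is heavier by the label mass.
* **Rounding.** Only report output is rounded (rt/Δrt/m/z/Δm/z 2 dp,
  Δintensity integer %, masses 5–6 dp, ppm 2 dp, defects 1 dp); filtering
  and ranking always use unrounded values.
* **Feature detection.** Traces are chained across consecutive scans by
  proximity to the running intensity-weighted mean m/z (tolerance 0.02
  amu, gap ≤ 0.05 min, ≥ 3 scans by default — artifact defaults, since
  the original instrument software's parameters are not published). A
  feature's rt and intensity are the trace apex (not area): the filter
  consumes intensity *ratios*, which are height/area agnostic, and
  published pair tables carry a single intensity per ion. The
  intensity-weighted mean m/z damps single-scan outliers.

## Open design points and how they were resolved

* **Grouping vs. metabolite counts.** Single-linkage co-elution grouping
  at 0.05 min merges two pioglitazone hits at rt 8.09/8.12 that are
  chemically unrelated (m/z 373.12 vs 272.13). Co-elution alone does not
  make an ion an in-source fragment, so `group_coeluting()` optionally
  splits members whose m/z difference from the group precursor matches no
  neutral-loss table entry; with the default loss table this yields eight
  pioglitazone metabolite groups while leaving the flurbiprofen rt-11.5
  fragment group (precursor m/z 259.07 with losses of 12.000 = C,
  30.0103 = CH2O and 44.9976 = CO2H) intact.
* **Neutral-loss labels.** The shipped loss table is mass-correct: the
  12.000 amu loss is labeled `C` and the 30.010 amu loss `CH2O`
  (descriptions elsewhere of these losses as "CH2" and "CH3O" do not
  match the mass differences).
* **Mass-only formula ranking.** Ranking is by $|\mathrm{ppm}|$ with
  deterministic ties (fewer heteroatoms, then Hill string). At m/z
  373.12111 under CHNOS bounds two compositions (C11H25N4O6S2,
  C25H15N3O) sit numerically closer than the true hydroxy-metabolite ion
  C19H21N2O4S (1.46 ppm). Instrument software resolves this with
  isotope-pattern scoring, which is deliberately out of scope here; the
  package therefore documents, and its tests exercise, *containment and
  ppm correctness* of the true composition rather than pretending
  mass-only search can rank it first.
* **Baselines.** The biotransformation list ships the common Phase-I/II
  deltas plus all two-step combinations and is an explicit, replaceable
  input. Mass defect filtering converts ion m/z to neutral mass by the
  proton correction before computing defects, so windows are comparable
  with neutral parent formulas. Under these defaults the hydroxypropanamide
  metabolite (defect 43.6 mDa, no matching list delta) escapes both
  baselines while the ordinary oxidation products are caught — the failure
  mode the twin-ion filter exists to fix. Note that the aldehyde-hydrolysis
  metabolite (−10.2 mDa) passes a ±40 mDa defect window and a double
  hydroxylation delta; its escape in the original study must reflect
  narrower, unpublished settings, which the package does not guess.
* **Reference-ion subtraction** (compound-only runs) is applied *before*
  filtering in the pipeline, configurably.

## The synthetic-data generator

`generate_paired_runs()` plants metabolite twins with known ground truth:
the labeled feature sits `label_shift` higher in m/z (default 4.0251, a d4
label), elutes earlier by U(0, 0.1) min (one-sided; a symmetric option
exists for stress tests), and carries a multiplicative intensity drift
U(0.5, 1.5) — an ion-suppression model, not additive noise. Matrix ions are
duplicated *identically* in both runs (shared biological background whose
mass shift is exactly zero, so they can never pass a tight filter), noise
ions are drawn independently per run (log-uniform intensities, m/z uniform
over 100–1000, rt over 1–15 min of a 20-min gradient), and a dominant
shared matrix ion provides the base peak so that relative intensities are
comparable across runs. Per-feature Gaussian m/z error (`mz_sigma`) proxies
instrument resolution; `generate_scans()` additionally expands every
feature into a Gaussian elution profile for end-to-end detector tests. All
randomness flows through one seed with the global RNG state restored
afterwards.

What the generator does *not* emulate: chromatographic tailing, isotope
envelopes, adducts beyond ±H, intensity-dependent mass error, and
correlated matrix structure (polymer series). Passing recovery tests on
synthetic data therefore demonstrates correctness of the filtering logic
under the stated noise model, not instrument-grade performance on real
data.

Test problem sizes: the recovery study uses 100 seeded replicates of the
default specification (8 planted twins, 50 matrix + 30 noise ions per run)
at `mz_sigma = 0`, where recall is 100% and no false pair occurs; the
low-resolution stress case uses 500 matrix + 500 noise ions per run at
`mz_sigma = 0.2` and a pinned seed, where widening `mass_tol` from 0.04 to
0.5 amu admits false background pairs with a count monotone in the
tolerance. Oracle-equivalence property tests run a few hundred random maps
of up to 50 features per run.

## Known limitations

* Singly charged ions only; no adduct tables beyond protonation states.
* Metabolites that lose the labeled site are invisible by design; the
  remedy (re-filtering at partial shifts, or core labeling such as 13C)
  is operational, not algorithmic.
* Mass-only formula ranking cannot separate isobaric compositions closer
  than the mass accuracy (see above).
* Constant-tolerance alignment presumes a shared gradient; no rt warping.
* The feature detector is a plain trace-chaining algorithm adequate for
  the filter's inputs, not a replacement for a full peak picker on
  profile data.
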