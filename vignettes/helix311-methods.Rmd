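---
title: "Methods: amphipathic 3-11 element detection and disordered-ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amphipathic 3-11 element detection and disordered-ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helix311)
```

This vignette is the package's own account of its models, parameters and
numerical choices: what is computed, which constants matter, what the
synthetic generators emulate, and where the design was genuinely open.

## 1. The detection model

Weak amphipathic helical elements in disordered proteins — the membrane-
interacting repeats of LEA proteins and apolipoprotein-like motifs — are
found in three stages.

**Helix-break segmentation.** Three breakers terminate a candidate helix:
proline; "continuous glycines", interpreted as runs of ≥ 2 G
(`G_run_min = 2`; a lone glycine is tolerated in helices, a run is not);
and runs of ≥ 4 polar/negative residues (`polar_run_min = 4`). The
polar/negative set is `{S, T, N, Q, C, H} ∪ {D, E}` — positives and
hydrophobics are excluded by construction, since K/R commonly support
membrane-binding interfaces and hydrophobics form the face itself. Break
residues belong to no segment, so no element can contain one.

**Window test.** Each break-free segment is scanned with a 7-residue
window (the minimal length of a credible amphipathic stretch — just over
two turns of a 3-11 helix). A window passes when

* its hydrophobic-face count (face set: residues with Fauchère–Pliška
  value > 0.25, i.e. `A C F I L M T V W Y`, keeping the weakly hydrophobic
  alanine and threonine) lies in `[face_min, face_max] = [2, 5]`;
* all face residues fall within a wheel arc of ≤ `arc_max = 180°`,
  with residue *i* at angle *i*·δ, δ = 1080/11° ≈ 98.18° (the 3-11 wheel:
  3 turns per 11 residues);
* its hydrophobic moment at the same angle is ≥ `µH_min = 0.2`
  (Fauchère–Pliška units).

The three-part test is this package's operationalization of classic
apolipoprotein-motif criteria, whose exact numeric thresholds are not
published in a reusable form; every constant is exposed in
`detect_params()`.

**Stitching and the slot filter.** Windows whose intervals overlap or abut
merge into maximal elements. An element must place hydrophobic residues on
3–5 *distinct* of the 11 wheel slots (slot of offset *i* = 3·*i* mod 11):
fewer slots means no real face, more means the face wraps around the
wheel. The distinct-slot count is invariant under shifts of the element
start, because shifting rotates all slots by a constant.

A subtlety worth recording: the element *count* is not monotone in
`µH_min`. Removing a mid-element window can split one element into two, so
tightening the threshold can increase the count while strictly shrinking
the set of covered residues. The tests assert the coverage property, which
is the true invariant of the stitching rule.

## 2. Element properties

For each element: mean hydrophobicity *H*; hydrophobic moment *µH*
at both 100° (the canonical α-helix angle used by HELIQUEST's equations;
this one feeds D by default) and 1080/11° (the wheel geometry used for
slots and arcs); net charge *z* with K/R = +1, D/E = −1 and histidine
neutral at the assumed pH (configurable); and the lipid discriminant
factor D = 0.944·µH + 0.33·z, which separates lipid-binding from
non-binding amphipathic elements — weak moments with acidic faces score
low. µH is normalized per residue (mean moment), matching the HELIQUEST
convention. Windowed charge tracks report NCPR and FCR over 10-residue
windows; |NCPR| ≤ FCR everywhere by construction.

The built-in disorder proxy is a FoldIndex-style score,
2.785·⟨H_KD⟩ − |⟨NCPR⟩| − 1.151 over a 51-residue window with
Kyte–Doolittle hydropathy rescaled to [0, 1], remapped to a pseudo-
disorder score clamp(0.5 − FI/2, 0, 1). It is a deliberately simple
charge-hydropathy classifier: adequate for separating disorder-biased from
globular compositions (which is all the pipeline asks of it), not a
substitute for a modern energy-based predictor. Externally computed tracks
are preferred whenever supplied.

## 3. Stratified statistics

`compare_by_localization()` runs, per property, a Kruskal–Wallis omnibus
test (midranks, tie correction, χ² reference; exact enumeration below
N = 10, Monte Carlo permutation reference via `kw_permutation_p()` at any
N) and all pairwise Wilcoxon rank-sum tests with common-language effect
sizes, plain differences of medians, and Holm adjustment within the
property family. Raw p-values are reported beside adjusted ones, because
published figure annotations often use unadjusted stars. The pairwise test
choice (rank-sum) and the Holm family are this package's decisions; the
omnibus test is standard for this analysis. The summary-statistic t test
(`unpaired_t()`, pooled or Welch) reproduces printed instrument
comparisons from means ± SD; where a publication's "±" could be SD or SEM,
SD is assumed — for the phase-transition example in the test suite this
choice reproduces the printed p-value.

## 4. The synthetic homolog families

`synth_family()` emulates the structure of a localization-resolved homolog
set, not its evolution. Each sequence is a disorder-biased background
(S/E/K/Q/G/D-rich, hydrophobics depleted, P and G frequent enough that
natural helix breaks occur every ~10 residues) carrying two planted
22-residue elements (two 11-mer repeats), each flanked by explicit proline
breakers so detected intervals cannot leak into the background.

The templates come in six index-matched variant pairs
(`element_variants()`): one archetype with a strong face (≥ 2 L/I/F) and
two basics per 11-mer for other/secretory sequences, one with a weak
A/T/V face and four basics for mitochondrial/chloroplast sequences. Each
pair was designed by direct search so its two hydrophobic moments agree
to < 10⁻⁴ scale units at both projection angles: the weak face of the
organellar variant is compensated by its stronger basic (negative-*h*)
hydrophilic side, which is exactly the physical reason the real trade-off
can leave µH invariant. Every planted element draws its variant index at
random, so all groups share the *same* moment distribution (spread
~0.36–0.47) while basic fraction and hydrophobicity differ sharply. Group
differences in those properties are therefore planted; the µH contrast is
null by construction, and the stratified tests reject it only at the
nominal rate. An earlier single-template design failed exactly here: with
near-deterministic per-group moments, even 10⁻³-scale template mismatch
and the group-specific second-order drift of mutation noise made the
"null" reject almost always — matching the distributions, not just the
means, is what makes the null honest.
Mutations (default 2% per element residue) are class-preserving — face
residues stay in the face set, hydrophilic residues stay hydrophilic, and
P/G are never introduced — so planted truth remains valid. Secretory
sequences get an N-terminal signal-peptide-like stretch built from
L/A/V/I/F only; with 6–7 face residues in every window it fails the face-
count criterion and cannot be mistaken for an amphipathic element.

What the families do *not* emulate: phylogenetic correlation between
sequences, indels, motif copy-number variation, and genuine disorder
tracks (the background is compositionally disordered, which the FoldIndex
proxy recognizes, but no per-residue disorder ground truth is planted).
Passing tests therefore show the pipeline resolves planted composition
contrasts at realistic effect sizes — not that it would resolve them on
any real homolog set.

## 5. The statistical-coil sampler

Backbone dihedrals are drawn per residue from four Gaussian basins —
β (−120, 135), PPII (−75, 145), α_R (−63, −43), α_L (57, 42), standard
deviations 10–25° — with default weights (β 0.32, PPII 0.42, α_R 0.21,
α_L 0.05); glycine gets widened basins and more α_L, proline a pinned
φ ≈ −65°. Backbones use ideal trans-peptide geometry (N–Cα 1.458 Å,
Cα–C 1.525 Å, C–N 1.329 Å, ω = 180°), so consecutive Cα–Cα distances are
3.8 Å by construction. Chains are grown residue by residue; a placement
whose Cα comes within 4.0 Å of any Cα ≥ 3 residues back redraws the local
dihedrals (up to 40 times) before the whole chain restarts. A residue is
flagged helical when φ ∈ [−90°, −30°] and ψ ∈ [−77°, −17°] — bounds chosen
to contain the α_R basin with ~2.5σ margin.

The weights were calibrated once so that 200-residue ensembles reproduce
the expanded-coil compaction expected for a disordered chain of that
length (mean Rg ≈ 44 Å). A known limitation, measured and accepted: with
Cα-only excluded volume at 4.0 Å — barely larger than the 3.8 Å virtual
bond — the apparent power-law exponent of Rg over N ∈ {50…400} is
≈ 0.545, slightly below the Flory self-avoiding value (≈ 0.588) and below
the 0.55 floor a fully excluded-volume ensemble would show. Calibration
scans over basin weights and widths move the mean Rg freely but leave the
exponent pinned near 0.545 whenever the mean is held in the realistic
40–48 Å range; Rosenbluth-weighted growth raises the exponent to ≈ 0.62
but with weight degeneracy that makes the mean unstable, so the plain
sampler is kept and the limitation documented rather than papered over.

## 6. Shift model and ensemble selection

The forward model is two-state and linear: predicted shift = random-coil
reference + helical propensity × full-helix offset, with literature-
typical offsets (Cα +2.6, Cβ −0.4, CO +1.7, N −1.5, HN −0.25 ppm) and
per-nucleus uncertainties (0.3/0.3/0.3/0.6/0.12 ppm) in `shift_model()`.
These are generic helix secondary-shift magnitudes, not fitted constants.
Random-coil references are a required input; `random_coil_table()`
provides typical synthetic values so the self-contained workflows run, and
real analyses should substitute their own corrected tables.

`ga_select()` evolves index-multisets of size M: tournament selection
(size 3), one-point crossover (p = 0.9), per-locus mutation (p = 0.02),
elitism 1 (hence monotone best fitness), population 64, stall after 50
flat generations. Because the forward model is linear in propensity, the
χ² of a candidate reduces to a per-residue quadratic in its flag average,
evaluated in O(L). `iterate_selection()` re-estimates per-residue basin
frequencies from each selection and regenerates a biased pool (desk
preset: 2,000 → 50 selected → 1,700 biased + 300 base → five rounds; the
full-scale preset mirrors the published 10,000/200/8,500 + 1,500/nine
rounds). Convergence is reported as the propensity change per
round; no hard threshold is imposed, since the published pipelines state
none. `select_with_rg()` adds an Rg restraint term
((⟨Rg⟩ − target)/σ)² — a deliberate reduction of a scattering-curve fit to
its compaction summary; no form factors are computed.

Problem sizes used in the tests (chains of 50–60 residues, pools ≤ 2,000,
three seeds) were chosen as the smallest at which recovery is meaningfully
testable: planted profiles (baseline 0.05, segment 0.6) are recovered with
RMSE < 0.015 noiseless and < 0.08 at 1σ shift noise, an order of magnitude
inside the acceptance tolerances.

## 7. Instrument formulas

All closed forms are evaluated exactly as printed in the field's methods
sections: Cs⁻¹ = −A·(dπ/dA) with central differences (optional
Savitzky–Golay smoothing; the derivative scheme is a numerical choice, so
a < 2% agreement against analytic derivatives of smooth synthetic
isotherms is part of the acceptance tests); h = A·exp(−R·t) by nonlinear
least squares with log-linear initialization and a profiled-amplitude
fallback for degenerate (non-decaying) data, flagged rather than hidden;
hetNOE = I/I₀ with first-order error propagation; anisotropy
r = (I∥ − g·I⊥)/(I∥ + 2·g·I⊥) with g = 1.171 as the default detector
calibration; DSC baseline = mean of the last 15 points ("well beyond the
phase transition"), Tm = global maximum of the corrected trace, secondary
peaks by prominence (≥ 10% of the main peak). Boundary maxima are flagged
unreliable. Units are declared per trace and never converted implicitly;
temperatures are °C throughout.

Absolute wet-lab numbers (transition temperatures of specific lipid
preparations, moduli of specific monolayers, anisotropies of stained
mitochondria) are not reproducible from first principles and are treated
only as *structural mirrors*: the generators plant effects of the reported
magnitude (e.g. a 0.32 °C Tm shift at σ = 0.04, n = 3) and the analyses
must resolve them at the reported significance.

## 8. Known limitations

* Detection thresholds are calibrated operationalizations, not published
  constants; reproducing a specific published element count on a specific
  protein may require tuning `µH_min`/`arc_max` within `detect_params()`.
* The coil sampler's excluded volume is Cα-only and weak (§5); its Rg
  *scaling exponent* undershoots a true self-avoiding walk even where the
  mean compaction is correct.
* The two-state shift model cannot represent β/PPII-specific shift
  signatures; recovered "propensity" is strictly the helical-basin
  fraction.
* The synthetic families carry no phylogenetic structure, so statistical
  power estimates on them do not transfer to strongly correlated homolog
  sets.
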