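---
title: "Simulating looped projective NMR of labile protons: models and design choices"
author: "lprosy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating looped projective NMR of labile protons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lprosy)
```

## The problem

Hydroxyl and amide protons of carbohydrates exchange with water at roughly
10–1000 s⁻¹ near room temperature.  This exchange destroys the polarization
transfer that 2D NOESY (cross-relaxation, rate σ) and TOCSY (scalar
coupling J under isotropic mixing) rely on, so OH-derived cross-peaks — up
to half of a glycan's potential ¹H information — are usually missing from
conventional spectra in water.  Looped projective spectroscopy (L-PROSY)
turns the same exchange into an asset: a frequency-selective
excite–evolve–store block addressing only the labile sites, followed by a
short mixing, is repeated l₁ times.  Between loops, exchange with the
enormous water reservoir re-polarizes the labile source, so each loop
deposits a fresh increment of labeled magnetization on the (untouched)
nonlabile destination, and the cross-peak accumulates toward its
thermodynamic limit instead of being capped by a single exchange-shortened
mixing.

This package simulates both experiments, optimizes their schedules, maps
the achievable enhancement over physical-parameter grids, and bundles the
structural-NMR analytics used around such measurements on glycans.

## Longitudinal model (NOESY engine)

Pool z-magnetizations follow the affine Solomon + Bloch–McConnell system
dM/dt = A·M + b built by `buildGenerator()`:

* off-diagonal `A[i,j] = σ[i,j] + k(j→i)`;
* diagonal `A[i,i] = −(R1ᵢ + Σⱼσ[i,j] + Σⱼ k(i→j))`;
* `b = −A·M_eq`, so thermal equilibrium is the exact, unique stable fixed
  point (all eigenvalues of A have negative real part for physical rates).

Exchange rates always satisfy detailed balance,
`k(a→b)·M_eq(a) = k(b→a)·M_eq(b)`; reverse rates are derived from that
relation at construction time, which makes the exchange sub-matrix conserve
total magnetization exactly (zero column sums).  Propagation uses the
matrix exponential of the augmented affine system (`Matrix::expm`), which
the test suite checks against a fine-step forward-Euler integration and
against the two-spin Solomon closed form.

Water is a finite but very large pool, 1000× the labile pool by default.
The published experiments do not state an effective water/solute
population ratio, so it is an explicit parameter: ~110 M water protons
against mM–100 mM solute hydroxyls puts the physical ratio at 10³–10⁶, and
at 10³ the simulations are already within 0.1 % of the clamped
infinite-reservoir limit (`clampWater = TRUE`), as one of the tests
verifies — larger values only cost conditioning.  Rates are s⁻¹, couplings
Hz, times s; no unit inference anywhere.

σ is an input, not computed from geometry and correlation times: negative
σ (fast tumbling, small molecules) gives cross-peaks opposite in sign to
the diagonal under the default display convention, and a single
`displaySign` switch is exposed for the opposite plotting convention.

## What a "loop" does

The selective pulses are ideal and instantaneous: perfect on the labile
targets, zero perturbation of water and CH pools.  The t₁ Ramsey evolution
amplitude-labels the source with cos(Ω·t₁); all amplitudes are reported at
the first t₁ increment, which is equivalent to comparing integrated peak
amplitudes and keeps lineshape out of the model entirely.

Within a loop the simulator propagates three objects:

1. the **physical magnetization** under the full affine flow (this is what
   exchange re-polarizes);
2. the **labeled magnetization** — the part of the signal carrying the
   fundamental t₁ modulation — under the homogeneous flow (it relaxes and
   keeps relaxing on the destination during later loops; nothing is
   frozen);
3. an **encoded-source ledger** that decays only through exchange out of
   the source.

At each loop start the labile source is projected: transverse memory is
destroyed, accumulated nonlabile z carries over, and the *fresh* label is
the source polarization delivered by exchange since the previous
projection (physical minus still-encoded).  The reasoning: re-encoding
magnetization that already carries a cos(Ω t₁) factor multiplies it by
another cosine, which moves it out of the fundamental harmonic that forms
the cross-peak, so only exchange-replenished polarization contributes new
signal.  Label that has leaked into water is treated as lost (diluted by
the ~10³ pool).  Two exact limits fall out of this bookkeeping and are
tested as identities: with l₁ = 1 and no exchange the L-PROSY run *equals*
the conventional run at the same mixing, and with no exchange at all the
optimal loop count is exactly 1 — looping cannot beat one long optimized
mixing without repolarization.

## Liouville model (TOCSY engine)

J transfer needs coherences, so the TOCSY engine works in the 16-member
orthonormal product-operator basis of the labile/nonlabile two-spin
subsystem, augmented by a scalar water z-magnetization (17 dimensions).
DIPSI2 is idealized as continuous isotropic mixing, H = 2πJ (I₁·I₂);
a `free` mode (offsets + weak coupling) exists for completeness.
Relaxation enters as R1/R2 decay per operator factor.  Exchange follows a
stochastic-jump model: every operator containing a labile-spin factor
decays at k_ex (uncorrelated replacement destroys coherences and two-spin
order — this *is* the J-averaging that kills conventional TOCSY at fast
exchange), while replacement magnetization enters only as z-polarization
from water.  The identity component is exactly conserved.  In the
no-exchange, no-relaxation limit the engine reproduces the isotropic
transfer closed form sin²(πJτ) to 10⁻⁸, and complete transfer at
τ = 1/(2J).

A three-spin relay is deliberately out of the model: the two-spin + water
system is what the enhancement claims rest on.

## Optimization and enhancement maps

Enhancement is always a ratio of *individually optimized* schedules.
Conventional mixing is optimized by a bracketing grid plus golden-section
refinement, capped at 400 ms — the experimental ~100 ms cap at fast
exchange emerges from the physics, it is not hard-coded.  The L-PROSY
schedule is a joint deterministic grid search over l₁ = 1…30 and per-loop
mixing 5–100 ms in 5 ms steps, refined ten-fold around the optimum
(published schedules such as 10 × 40 ms and 14 × 35 ms sit inside this
box).  There is no randomness anywhere in the optimizers, and maps are
invariant under grid-axis reordering.

```{r map, eval = FALSE}
sys <- sugarSpinSystem(R1 = 0.5)
enhancementMap(sys, kexGrid = c(10, 100, 1000),
               couplingGrid = c(-0.2, -0.05, -0.01), experiment = "noesy")
```

With realistic saccharide parameters (k_ex up to 1000 s⁻¹, σ down to
−0.2 s⁻¹, R1 0.5–2 s⁻¹) the NOESY map exceeds an order of magnitude at its
maximum, and TOCSY enhancement at the fast end of the exchange range
exceeds 4× — both recomputed by the test suite.  Two qualitative features
deserve a note:

* enhancement *increases* with k_ex across the 10–1000 s⁻¹ range and falls
  again only at substantially faster exchange (the bell shape is tested on
  a grid extended to 3 × 10⁴ s⁻¹), because the relative gain saturates
  once every loop is fully re-polarized;
* smaller J earns a larger *relative* TOCSY enhancement: at large J the
  conventional experiment can still complete an appreciable fraction of
  its sin² transfer before the coupling is averaged, while for weak
  couplings it cannot — looping with re-polarization restores most of the
  difference.

## Structural analytics

These implement the standard quantitative steps used alongside such
experiments on glycans:

* **Karplus analysis** — `J(ω) = 0.48 + 10.18 cos²ω − 0.03 cosω` Hz by
  default (`karplusParams()`), with a numerical inverse
  (`torsionCandidates()`) returning merged, wrap-aware torsion intervals.
  At ω = ±90° the curve gives 0.48 Hz, which is why small observed ³J
  (< 2 Hz) reads as a ±90° torsion — and why that torsion is degenerate,
  which is what the `degenerate` flag of `buildRestraints()` encodes by
  emitting both branches.
* **NOE effective distances** — `⟨r⁻⁶⟩⁻¹/⁶` over ensemble frames, the
  standard cross-relaxation average (an occasionally seen rendering of the
  exponent as ⟨r^(−1/6)⟩^(−1/6) is a typographical slip; the r⁻⁶ power
  mean is the physically meaningful average and the one implemented).
  Multi-proton selections (H3 axial/equatorial, H9 pro-R/pro-S) use the
  per-frame shortest distance.
* **Hydrogen bonds** — geometric definition, d(D···A) ≤ 3.0 Å and
  θ(D–H···A) ≥ 135°, both *inclusive* at the boundary (a documented
  convention; the angle lives at the donor hydrogen, 180° = linear).
  Occupancies are frame fractions and tightening criteria can only lower
  them.
* **Restraint export** — distance ± 1 Å, torsion target ± 30° wrapped to
  [−180°, 180°).
* **Arrhenius scaling** — k(T) = k_ref·exp(−Ea/R·(1/T − 1/T_ref)); no
  activation energy for OH exchange is implied by the modeled data, so Ea
  is always an explicit input.
* **Diffusion** — Stejskal–Tanner fits seeded by the exact log-linear
  solution and refined with Levenberg–Marquardt; D ratios convert to
  hydrodynamic-radius ratios (Rh_analyte/Rh_ref = D_ref/D_analyte).

## Ensemble geometry

Superposition uses the SVD (Kabsch) solution with reflection correction;
an independent quaternion-eigenvalue oracle in the tests agrees to 10⁻⁸.
2D-RMSD maps are all-versus-all superposition RMSDs on an atom subset
(selection helpers mirror the ring-atom subsets, e.g. 28 atoms
C1–C6 + O6 over four residues), symmetric with zero diagonal.  Cutoff
clustering is *single-linkage* (connected components under the cutoff): the
published analysis inspects the map visually, and a deterministic,
parameter-free rule was needed — single linkage is the closest formal
analogue of "regions connected below 2 Å" and is trivially swappable.
Representative models average 11 consecutive frames (anchor ± 5) after
superposing each frame onto the anchor — superpose-then-average, so
rotational scatter does not smear the mean; the sources are silent on this
point and raw averaging would bias the reference.  Torsion population maps
use 5° bins over [−180°, 180°) (72 marginal bins) with exact
normalization.

## Synthetic data

`generateSyntheticSpinSystem()` draws the hydroxyl exchange rate
log-uniformly over 10–1000 s⁻¹ (`sugar-OH` preset; `amide` uses
1–100 s⁻¹), with σ = −0.05 s⁻¹, J = 5 Hz and R1 = 1 s⁻¹ as the
small-molecule defaults used throughout the enhancement analysis.
`generateSyntheticEnsemble()` produces rigid-template ensembles: a single
well, a two-state mixture (two templates ~4.7 Å apart in superposition
RMSD, i.i.d. states with a chosen mixture fraction, Gaussian coordinate
noise), or a uniformly drawn central torsion.  Everything is deterministic
under a seed and no global RNG state leaks.

What these fixtures emulate — and what they do not: they give known ground
truth for mixture fractions, torsion distributions and H-bond geometry,
so that passing tests certify the *estimators*.  They are not molecular
mechanics: no excluded volume, no correlated inter-frame dynamics (except
the block construction used for windowed-reference tests), no force-field
realism.  Agreement on these fixtures therefore says nothing about the
conformational content of any real trajectory, only that the analysis
operators compute what they claim.

## Problem sizes and numerics

The shipped tests run the NOESY enhancement map on a 4 × 3 × 3
(k_ex × σ × R1) grid, TOCSY optimizations on single systems, ensemble
statistics at up to 500 frames × 10 atoms, and Euler cross-checks at step
sizes 2 × 10⁻⁷–5 × 10⁻⁸ s chosen so that the first-order integrator's own
error sits below the 10⁻⁶ comparison tolerance.  These sizes were chosen
as the smallest that exercise every claim; all engines scale to finer
grids unchanged.  Degenerate inputs are refused loudly: exchange between
two nonlabile pools, non-labile selective targets, zero interatomic
distances, collinear superposition subsets, non-decaying diffusion data
("no transfer" and "undefined enhancement" are distinct classed
conditions, never silent zeros).

## Known limitations

* No lineshape or FID synthesis, no water suppression, no phase cycling,
  no shaped-pulse imperfections: selectivity is ideal, so selectivity
  breakdown when the OH resonance broadens into water at extreme exchange
  is outside the model (the heteronuclear transfer delay of the
  HSQC-coupled variants, Δ = 1/(4·J_HC), is documented but that block is
  not simulated).
* The TOCSY engine models one labile/nonlabile pair plus water; relay
  transfer is out of scope.
* R2 affects only the Liouville engine; the longitudinal NOESY model
  ignores it by construction.
* Diagonal-peak enhancements are reported but are not a validated
  quantity — receiver-setting equivalence between the compared experiments
  cannot be established from the modeled information alone.
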