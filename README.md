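# lprosy

Simulation and analysis toolbox for NMR of **labile protons** — the
hydroxyl and amide ¹Hs that exchange with water at 10–1000 s⁻¹ and
therefore vanish from conventional 2D NOESY/TOCSY spectra of glycans in
aqueous solution.

The core of the package is a magnetization-transfer model of **looped
projective spectroscopy (L-PROSY)**: instead of one long mixing period, a
frequency-selective excite–t₁–store block on the labile sites plus a short
mixing is repeated l₁ times, and chemical exchange with the water
reservoir re-polarizes the labile source between loops so that cross-peaks
accumulate toward their thermodynamic limit.

Two engines implement the physics:

* **NOESY (longitudinal) engine** — Solomon cross-relaxation plus
  Bloch–McConnell exchange, dM/dt = A·M + b with
  A[i,j] = σᵢⱼ + k(j→i), A[i,i] = −(R1ᵢ + Σσᵢⱼ + Σk(i→j)) and
  b = −A·M_eq, propagated by exact matrix exponentials; detailed balance
  k(a→b)·M_eq(a) = k(b→a)·M_eq(b) is enforced by construction.
* **TOCSY (Liouville) engine** — the labile/nonlabile pair in the
  16-operator product basis plus a scalar water reservoir, with idealized
  isotropic mixing H = 2πJ(I₁·I₂) and a stochastic-jump exchange
  superoperator (labile coherences decay at k_ex; replacement enters as
  water z-polarization).  The no-exchange limit reproduces the sin²(πJτ)
  transfer closed form.

On top sit deterministic schedule optimizers and enhancement maps over
(k_ex, σ or J, R1) grids, and the structural-NMR analytics used around
such experiments on glycans: Karplus ³J evaluation and inversion
(J(ω) = 0.48 + 10.18 cos²ω − 0.03 cosω Hz by default), ⟨r⁻⁶⟩⁻¹/⁶ NOE
effective distances, geometric hydrogen-bond detection (d_DA ≤ 3.0 Å,
θ_DHA ≥ 135°), restraint tables (±1 Å, ±30°), Arrhenius exchange scaling,
chemical-shift temperature coefficients, Stejskal–Tanner diffusion fits
and hydrodynamic-radius ratios, Kabsch superposition, 2D-RMSD maps with
single-linkage cutoff clustering, 11-frame averaged representative models
and 5°-binned torsion population maps for multi-MODEL PDB ensembles.

## Worked example

How much does looping buy for a TOCSY cross-peak of a sugar hydroxyl at
the fast end of the exchange range (k_ex = 1000 s⁻¹, ³J = 5 Hz,
R1 = 1 s⁻¹), with both schedules individually optimized?

```r
library(lprosy)

sys  <- sugarSpinSystem(kex = 1000, J = 5, R1 = 1, R2 = 30)
conv <- optimizeConventionalMixing(sys, c("OH", "CH"), "tocsy")
lp   <- optimizeLprosySchedule(sys, c("OH", "CH"), "tocsy")

conv$tau; conv$amplitude
#> 0.0097...      4.63e-04
lp$loops; lp$tau; lp$amplitude
#> 30             0.0055    1.21e-02
lp$amplitude / conv$amplitude
#> 26.3
```

Exchange averaging caps the conventional experiment at a ~10 ms mixing and
a cross amplitude of 4.6 × 10⁻⁴ of the source equilibrium; thirty short
loops, each re-polarized through exchange, accumulate 1.2 × 10⁻², a
26-fold enhancement.  A single simulated schedule looks like this:

```r
pa <- runLprosyNoesy(sugarSpinSystem(kex = 500),
                     sequenceSchedule("lprosy", "OH",
                                      mixingTime = 0.04, loops = 10))
peakTable(pa)
#>   source destination amplitude experiment mixing loops
#> 1     OH          OH  0.000985     lprosy   0.04    10
#> 2     OH          CH -0.000831     lprosy   0.04    10
```

The negative OH→CH amplitude is the fast-tumbling (σ < 0) cross-peak sign
under the default display convention.  The same engines drive
`enhancementMap()`, which scans (k_ex, σ, R1) grids with both schedules
re-optimized per cell; with realistic saccharide parameters its maximum
exceeds an order of magnitude.

A thin command-line wrapper covering simulation, maps, Karplus/torsion
queries, NOE distances, H-bonds, restraints, RMSD maps, clustering,
torsion maps, diffusion fits and fixture generation ships at
`system.file("scripts", "lprosy-cli.R", package = "lprosy")`:

```sh
Rscript inst/scripts/lprosy-cli.R karplus --omega 90
#> J(90 deg) = 0.4800 Hz
```

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/lprosy-methods.Rmd`) explains the physical model, the
loop/projection bookkeeping, all default parameters and their rationale,
the numerical tolerances, and what the synthetic fixtures do and do not
establish about real data.
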