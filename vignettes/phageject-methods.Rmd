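---
title: "Models and methods behind phageject"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phageject}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phageject studies the directionality of DNA ejection from a bacteriophage
capsid: whether the genome end that was packaged *first* is also the first to
leave (FIFO) or whether the last-packaged end leads (LIFO), and how the two
pathways differ in how much DNA is ultimately ejected. The package has four
layers — a coarse-grained Langevin simulator of packaging/resting/ejection, an
ensemble-statistics layer, a sequence-composition → rigidity model, and a
single-molecule orientation caller with its synthetic-data generator. This
vignette records the models, the conventions, and the design decisions, in the
package's own words.

## 1. The chain model

The DNA is a Kremer–Grest bead–spring chain of `n = 200` monomers in reduced
units: monomer diameter σ (nominally 5 nm ≈ 136 bp of B-DNA at 0.34 nm/bp),
energy ε = k_BT, mass m, time τ = √(mσ²/k_BT).

* **Bonds** — FENE springs plus shifted WCA repulsion,
  U_b(r) = −(K R₀²/2) ln[1 − (r/R₀)²] + U_WCA(r), with K = 30 k_BT/σ² and
  R₀ = 1.5 σ. The logarithmic divergence at R₀ makes bonds uncrossable in
  practice; the engine aborts (rather than silently continuing) if a bond ever
  reaches R₀.
* **Excluded volume** — the purely repulsive WCA potential,
  4ε[(σ/r)¹² − (σ/r)⁶] + ε below the 2^{1/6} σ cutoff, between all non-bonded
  monomer pairs, monomer–shell pairs and monomer–wall contacts.
* **Bending** — U_a = K_a (1 + cos θ) at every interior monomer, with θ the
  interior angle of the bonded triplet. **Convention:** a straight chain
  (θ = π) costs zero and a fold-back costs 2 K_a. The opposite reading of
  "angle between two neighboring bonds" would invert the stiffness, so the
  convention is fixed here explicitly and tested. K_a = 10 k_BT together with
  the mean bond length b ≈ 0.97 σ gives a persistence length close to 10 σ =
  50 nm, the accepted value for double-stranded DNA. (For a discrete chain
  ⟨cos φ⟩ = coth K − 1/K, so l_p = −b/ln⟨cos φ⟩ ≈ 9.2 σ at K = 10; the
  simulator's measured value, 9–10 σ, sits inside the ±15% band used in the
  tests.)
* **Two-block rigidity** — the first half of the chain (the first-packaged,
  GC-rich moiety) uses K_F, the second half K_L, assigned by the triplet's
  centre monomer. Pairs (K_F, K_L) = (10, 10) … (11.5, 8.5) keep the mean at
  10 k_BT while scanning the relative rigidity r = (K_F − K_L)/K_L from 0 to
  0.35.

Integration is BAOAB Langevin velocity-Verlet with dt = 0.005 τ. The friction
coefficient is not fixed by the study design; 1.0 m/τ, the customary value for
Kremer–Grest melts and solutions, is the default and is configurable. With the
thermostat off and friction zero the scheme reduces exactly to velocity
Verlet, which is how the NVE energy-conservation check is run. Thermal noise
is generated by a ziggurat normal sampler on top of xoshiro256++, seeded per
phase from the trajectory's master seed, so packaging, resting and ejection
draw from independent reproducible streams and a change of resting time does
not perturb the packaging noise.

## 2. Capsid, portal and protocol

* **Capsid** — the interior radius follows from the packing-fraction
  definition φ = n σ³/(8 R_c³) (total monomer volume over interior volume at
  full packaging): R_c = 3.47 σ at φ = 0.6 and 3.97 σ at φ = 0.4. The shell is
  784 immobile WCA particles on a Fibonacci sphere. **Geometry convention:**
  shell particle centres sit at R_c + 1 σ, so that monomer *centres* can roam
  essentially the whole interior sphere of radius R_c. Placing the shell at
  R_c + σ/2 instead (so that centres are excluded beyond ≈ R_c − σ/2) makes
  the effective density at "full" packaging so high that the last few monomers
  cannot be inserted at the stated packaging force — packaging reproducibly
  stalls at ~196/200 — so that realization is rejected on feasibility grounds.
  Monomer centres never exceed R_c + σ/2 under the chosen convention.
* **Portal** — a square channel, inner width 1.6 σ and length 10 σ, attached
  over a polar opening in the shell. The four walls are finite rectangles with
  WCA repulsion of range 2^{1/6}·0.5 σ measured as true distance to the
  rectangle (edge-continuous, so no discontinuous field at the channel
  mouths). The shell opening has radius 1.45 σ so that the channel, not the
  rim particles, is the constriction; the rim still seals the annular gap
  around the channel's exterior. Because the walls are geometrically thin,
  bond *midpoints* interact with them as well — otherwise two bonded monomers
  can straddle a wall at a cost of ~2 k_BT and the chain leaks through the
  portal wall. The channel admits only a single strand (no hairpins), which is
  why the first monomer to exit is always a chain end.
* **Blockage** — a removable WCA disc across the channel's inner mouth,
  present from the end of packaging until the start of ejection.
* **Packaging** — the first 10 monomers start inside the channel; the
  remaining 190 are grown as a self-avoiding walk outside. A packaging force
  f_p = 10 k_BT/σ acts along the channel axis on every monomer whose centre is
  inside the channel. Each time 50 monomers have entered the capsid the force
  is switched off, the monomers currently in the channel are frozen in place,
  and the rest of the chain relaxes for τ_stall = 500 τ (three stalls per
  trajectory). Packaging ends when all 200 monomers are inside the capsid;
  trajectories that fail a step budget are flagged and excluded (counted).
* **Resting** — plain dynamics for τ_rest ∈ [0, 1500 τ] with the blockage in
  place; a leak check asserts that no monomer is outside.
* **Ejection** — blockage removed; a resisting force f_r = 0.35 k_BT/σ,
  standing in for the osmotic pressure that truncates in-vitro ejection, acts
  toward the capsid on monomers in the outermost 2 σ of the channel. The index
  of the first monomer to cross the channel's outer plane is `i_exit`; FIFO
  means `i_exit` in the first chain half. The ejection fraction φ_e(t) counts
  monomers **outside both the capsid and the portal** — the ejected coil piles
  up just outside the exit and wobbles across the outer plane, so a
  plane-based count shows spurious retractions of up to 0.2. The wait for the
  first exit is budgeted by t_max = 5000 τ (trajectories with no exit are
  reported as pathway "none" and excluded from P_FIFO, never dropped
  silently); once ejection has begun, every trajectory runs for the same
  post-onset window of 4000 τ, or until two consecutive 500 τ windows of φ_e
  differ by less than 0.005, whichever comes first. φ_c is the mean of φ_e
  over the final 10% of the run; the matched post-onset window is what makes
  φ_c comparable across trajectories whose ends took very different times to
  find the portal.

**What φ_c means here.** With a resisting force of 0.35 k_BT/σ over a 2 σ
zone, the work to push one monomer past the resisting region is ~0.7 k_BT, so
arrest is thermally leaky: given unbounded time the chain eventually ejects
completely (verified by 15 000 τ runs). φ_c is therefore an operational
plateau on the 5000 τ window — the same operational sense in which a
fixed-duration simulation reports a "converged" value — and pathway
comparisons of φ_c are made at matched windows. At desk scale (tens of
trajectories) the between-trajectory spread of φ_c is large (±0.15), dominated
by the waiting time for a chain end to find the portal and by burst-like
translocation; the package therefore treats φ_c orderings as ensemble-mean
statements, not per-trajectory ones.

## 3. Sequence composition → rigidity

The λ-like genome splits into a GC-rich left region (fraction of genome
length w_GC = 0.45, GC fraction γ_GC ≈ 0.53) and an AT-rich right region
(w_AT = 0.55, γ_AT ≈ 0.47). A statistical terpolymer model maps GC content to
persistence length, l_p(γ) = (23 + 23 γ + 26 γ²) + c nm, with c an unknown
additive constant that cancels in differences. Between γ = 0.60 and 0.30 the
model gives 13.92 ≈ 14 nm.

For γ = 0.53 vs 0.47 the difference-of-squares arithmetic gives Δl_p =
2.94 nm, while the value quoted alongside the published 53/47 nm region
estimates is 5.9 nm (and a printed "squared-difference" simplification would
give 1.47 nm). The arithmetic cannot be reconciled from the text, so the
pipeline exposes both routes (`delta_lp_source = "quoted"` or `"formula"`) and
defaults to the quoted 5.9 nm, which reproduces the downstream numbers:
solving {l_p,GC − l_p,AT = 5.9; 0.45 l_p,GC + 0.55 l_p,AT = 50} gives
(53.2, 47.3) → (53, 47) nm and r = (53 − 47)/47 ≈ 0.13. Persistence length
maps to the bending constant via the worm-like-chain discretization
l_p ≈ K_a σ/k_BT, and `bending_constants()` realizes a target r at fixed mean
K: K_F = 2 mean_K (1+r)/(2+r), K_L = 2 mean_K/(2+r), e.g. r = 0.35 →
(11.5, 8.5) k_BT.

## 4. Orientation calling

A stretched, surface-anchored molecule is observed as a 1-D AT-stain
intensity profile with the capsid at pixel 1. **Geometry convention:** the
capsid anchors the unejected DNA, so the genome end that ejected *first* is
the *distal* (free) end. For a molecule with ejected fraction f, the FIFO
hypothesis predicts the barcode of genome segment [1, fL] read distal→capsid
(i.e. reversed), the LIFO hypothesis the segment [L−fL, L] read forward. The
generator and the caller share this single convention constant.

The expected barcode is the windowed AT fraction (1000 bp window), minus a
binding baseline, clipped at zero, mapped onto the measured pixel span and
blurred with a 0.3 μm Gaussian point-spread function. The baseline default is
0.30 (not 0.50): AT-specific probes still bind the AT-poorer region of a
λ-like genome — observed experimentally as a thin-but-visible line — and a
0.50 baseline would zero out the entire GC-rich half, making ~half of the
0.4-fraction FIFO molecules constant (uninformative) profiles. Both the
baseline and the clip are configurable.

Calling measures the molecule length (longest run above background + 3
noise-SD, background estimated from the dimmest 10% of pixels), estimates
f from it, builds both candidate barcodes, smooths the measured trace with
the same 0.3 μm kernel (a matched filter; without it, weak-contrast molecules
— disproportionately true-LIFO ones, whose block boundary sits near the
capsid end for λ-like composition — fail the quality threshold and their
exclusion biases cohort FIFO percentages upward by ~6 points), and reports
the orientation with the larger Pearson correlation. Calls are `ambiguous`
when the two coefficients differ by < 0.05 or the best is < 0.3; ambiguous
molecules are excluded from percentages but always counted.

For *cohort* estimation of the FIFO percentage, calls are additionally
restricted to molecules long enough that **both** candidate barcodes span the
genome's composition boundary (estimated fraction ≥ 1 − boundary_fraction +
0.05, i.e. ≥ 0.60 for a boundary at 45%). Below that length one pathway's
candidate is a near-featureless single-block barcode, so score-based
ambiguity rejects true molecules of that pathway far more often than the
other (observed per-genome exclusion asymmetries up to 14% vs 1%), biasing
the cohort FIFO percentage by several points. A cut on measured length is
independent of the true pathway and restores calibration: across replicate
cohorts the standardized estimator error has mean ≈ 0 and SD ≈ 1. Single
molecules of any length can still be scored by setting
`min_callable_fraction = 0` (the default for `call_direction()` itself).

Candidate barcodes are scaled onto the measured pixel span, which makes the
two candidates of a *full-length* molecule exact mirror images; profile
reversal then swaps the two correlations to machine precision, the property
the reversal-consistency test checks. For partial molecules the two
hypotheses address different genome segments, so reversal generally produces
an honestly ambiguous call rather than a mirrored one.

Length conversions: contour length = 0.34 nm/bp (48 502 bp → 16.49 ≈
16.5 μm); heavy intercalator staining lengthens DNA by ~50% (16.5 × 1.5 =
24.8 μm); ejected fractions are reported against a 17.25 μm full-length
control. The generator's default stretch factor 1.05 reflects that the
air-immobilized control (17.25 μm) runs slightly over the crystallographic
contour length.

## 5. The synthetic-data generator

`synth_genome()` draws residues independently with block-specific GC
probability (defaults 0.53/0.47, boundary at 45% of length) — it emulates the
two-block composition and nothing else (no repeats, no local motifs, no
correlated composition). `synth_molecule_profile()` builds the expected
barcode for a chosen pathway and ejected fraction, adds a constant background
at 10% of peak signal and Gaussian noise with SD = peak/SNR, and appends
background-only padding beyond the distal end. `synth_cohort()` draws pathway
labels Bernoulli(true_p_fifo) and ejected fractions from a truncated normal
(mean 0.675, SD 0.04, bounds 0.55–0.80, matching the 60–75% band observed for
in-vitro ejections); the experimental design unit is three sets of 50
molecules per condition. The noise model is deliberately minimal — additive
Gaussian with a flat background — because no per-pixel noise characterization
of the real images is available; SNR values are conventions. Passing the
truth-recovery tests therefore shows the *pipeline* is calibrated under this
noise model, not that real micrographs meet it.

## 6. Numerical choices and degenerate inputs

* Window/step for AT profiles default to 1000/100 bp; `N` bases are excluded
  from window denominators and an all-N window is an error.
* Wilson score intervals (95%) for all pathway proportions; they behave at
  zero counts, where Wald intervals collapse.
* φ_e monotonization for the energy-vs-φ_e landscape uses the running
  maximum; raw series are retained in the trace records.
* Non-converged and non-ejecting trajectories are reported in their own
  columns, never silently dropped.
* Wall kicks are force-capped at 500 k_BT/σ: the cap is far above any force a
  healthy configuration produces and only bounds the damage of a pathological
  initial contact.
* Free-chain runs start from a discrete-WLC conformation (bond angles drawn
  from the bending Boltzmann weight, redrawn on excluded-volume clashes); a
  straight-rod start keeps its global orientation far longer than any
  affordable equilibration window and inflates apparent persistence lengths.
* The BAOAB integrator's kinetic temperature carries a known O(dt²) offset
  (~0.6% at the bond stiffness used here); the equipartition check allows 3
  standard errors plus 1% for it. Configurational observables (persistence
  length, φ_c, energies) do not inherit this offset at leading order.
* Rounding of reported values follows round-half-to-even (R's `round`).
* Degenerate inputs error loudly: FENE bonds at r ≥ R₀ abort the trajectory
  with a diagnostic; constant intensity profiles are rejected as
  uninformative; zero-length genomes, inverted weights and out-of-range GC
  fractions are rejected at construction.

## 7. Problem sizes used by the tests

The packaged test-suite runs the study at reduced scale, chosen so the whole
suite completes on a single CPU in well under half an hour: free-chain checks
use 50–200 monomers and 10²–10⁴ τ; ensemble checks use 6–16 trajectories per
condition (the full-scale claims are about 2000-trajectory ensembles; the
package's `run_experiment_grid()` reproduces those at full scale given the
hours of compute they need). With n per pathway this small, φ_c comparisons
are made with generous bands (±0.15) around the published values and the
orderings are checked as ensemble means. Truth-recovery for the orientation
pipeline runs at full cohort scale (100 replicates × 200 molecules), which is
cheap.

## 8. Known limitations

* No hydrodynamics, electrostatics, twist, or explicit tail-tube
  translocation; the resisting force is a constant stand-in for osmotic
  pressure, not a pressure model.
* One monomer ≈ 136 bp: sequence is represented only through the two-block
  bending constants; there is no base-pair-resolution mapping.
* φ_c is an operational plateau (Section 2); quantitative φ_c values depend
  on the window and on realization details of the portal that the study
  design leaves open.
* The published conversion between the motor force in pN and the reduced
  packaging force is dimensionally inconsistent with σ = 5 nm at room
  temperature; the reduced value 10 k_BT/σ is used as given and no physical
  force conversion is asserted anywhere in the package.
* The synthetic genome's independent-draw composition makes barcode
  fluctuations slightly *less* informative than real λ DNA's long-range
  composition structure, so classifier accuracies here are, if anything,
  conservative for genomes with stronger block contrast.
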