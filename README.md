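# phageject

Which end of a packaged phage genome leaves the capsid first? Bacteriophage λ
packages its 48,502-bp genome into the capsid through a narrow portal; on
infection (or in-vitro triggering) the DNA is ejected through the same portal.
The textbook expectation is last-in-first-out (LIFO): the end packaged last
sits at the portal and leads the way out. Single-molecule AT-stain imaging of
ejected molecules instead shows both ends leading with nearly equal
probability, implying the tightly packed genome can still rearrange its ends
inside the capsid. `phageject` provides the computational side of that study
as a reusable R package:

* a **coarse-grained Langevin simulator** — a 200-monomer Kremer–Grest
  FENE/WCA bead–spring chain with a two-block bending potential
  (U_a = K_a(1 + cos θ); K_F for the first-packaged half, K_L for the second),
  packaged by a force f_p = 10 k_BT/σ through a 1.6σ × 1.6σ × 10σ portal
  channel into a 784-particle spherical capsid (packing fraction φ = 0.4 or
  0.6), rested for τ_rest, and ejected against a resisting force
  f_r = 0.35 k_BT/σ;
* **ensemble statistics** over ejection trajectories: P_FIFO (probability the
  first-packaged end exits first, from the index `i_exit` of the first monomer
  through the portal) with Wilson intervals, converged ejection fractions φ_c
  per pathway, and the total-energy landscape E(φ_e);
* a **sequence → rigidity model**: windowed AT profiles, the terpolymer
  persistence-length model l_p(γ) = 23 + 23γ + 26γ² + c (nm), region
  persistence lengths from Δl_p and the genome-wide mean
  (0.45 l_p,GC + 0.55 l_p,AT = 50 nm), relative rigidity r = (K_F − K_L)/K_L,
  and bending constants at fixed mean;
* an **orientation caller** for 1-D AT-stain intensity profiles of stretched,
  capsid-anchored molecules — Pearson correlation against the expected genome
  barcode in both orientations — plus a **synthetic-data generator**
  (two-block genomes, noisy molecule profiles, whole cohorts with ground
  truth).

## Worked example

```r
library(phageject)

## sequence -> rigidity (the analytic pipeline)
rr <- region_rigidity()   # gamma 0.53/0.47, weights 0.45/0.55, mean 50 nm
rr
#> <region_rigidity>
#>   gamma (GC-rich / AT-rich): 0.530 / 0.470, weights 0.45 / 0.55
#>   delta l_p = 5.90 nm (quoted); l_p = 53.24 / 47.34 nm
#>   relative rigidity r = 0.1246; K_F = 10.587, K_L = 9.413 k_BT
round(relative_rigidity(11.5, 8.5), 2)
#> [1] 0.35
round(contour_length_um(48502), 1)       # full contour, 0.34 nm/bp
#> [1] 16.5
round(stain_corrected_length(16.5, 1.5), 1)  # +50% intercalator lengthening
#> [1] 24.8

## one simulated trajectory: package -> rest -> eject
p <- sim_params(packing_fraction = 0.6, K_F = 11.5, K_L = 8.5,
                tau_rest = 1500)
tr <- simulate_trajectory(p, seed = 301)
tr
#> <ejection_trace> pathway FIFO (i_exit = 1), phi_c = 0.698 (not converged), 5161 tau

## orientation calling on synthetic molecules with known truth
co <- synth_cohort(cohort_spec(n_molecules = 50, true_p_fifo = 0.5,
                               snr = 5, seed = 1))
calls <- call_cohort(co)
s <- cohort_summary(calls)
round(s$percent_fifo, 1); s$n_called
#> [1] 52.1
#> [1] 48
```

`i_exit = 1` means the first-packaged end led the ejection (FIFO); φ_c is the
plateau value of the ejection fraction, i.e. 1 − φ_c of the chain stays in
the capsid against the resisting force ("not converged" flags that the strict
stationarity heuristic had not fired by the end of the fixed post-onset
window — φ_c is then the operational plateau over the final tenth of the
run; see the methods vignette). In the cohort example, 48 of 50
synthetic molecules receive a confident orientation call and the estimated
FIFO percentage brackets the simulated truth of 50%.

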