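# wpfx — whole-pattern fitting for serial femtosecond nanocrystallography

Serial femtosecond crystallography (SFX) merges diffraction snapshots from
thousands of protein nanocrystals into one data set. When crystals are only
tens of unit cells across, the finite-lattice interference function
`L_N(t) = sin²(πNt)/sin²(πt)` broadens every Bragg reflection and spills
intensity between them, so the standard extraction — integrating pixels
inside a mask around each Bragg position — mixes neighbouring tails into
every integral. wpfx implements the alternative: treat the merged pattern
as a continuous function of the scattering vector **q** and fit it whole,
as Le Bail decomposition does for 1D powder data, extended to 2D
reciprocal-lattice planes.

The fitted model is

    I_calc(q) = Σ_k |F_k|² Φ_k(q − q_k)

with a shared extended pseudo-Voigt profile Φ (a separable product of two
1D pseudo-Voigts, mixing weights η_x, η_y and FWHM widths Γ_G, Γ_L per
reciprocal axis). Each refinement cycle re-estimates the squared
structure-factor moduli |F_k|² by solving the linear system **I = P F**,
where `P_ji = Φ_i(q_j − q_i)` encodes peak overlap at the Bragg positions
(Gaussian elimination; conditioning monitored via the singular-value
ratio), and refines the profile parameters by minimising
`Ψ = Σ_i w_i (I_obs,i − I_calc,i)²` over *all* pixels. Extracted moduli are
put on the reference scale by a Wilson fit (scale k, overall B).

The package also ships the pieces needed to benchmark the method end to
end: a finite-lattice simulator for merged ensembles of log-normal-sized
needle crystals in the (hk0) plane, the competing circular-integration
extractor with Wilson scaling, radius sweeps of mean relative moduli
errors, and the decomposition of the fitted model into own-peak and
neighbour contributions around any reflection. Intended users are
methods-oriented crystallographers studying extraction accuracy for
nanocrystal data.

## Worked example

Simulate a merged pattern for 200 needle crystals (means 10 × 30 unit
cells, log-normal σ = 0.25) of a synthetic tetragonal test cell
(a = b = 79.959 Å) on a 340×340 grid to 5 Å, fit it, and compare
extraction accuracies:

```r
library(wpfx)
cell  <- unit_cell(79.959, c = 90.419)
atoms <- make_test_cell(7, 40, cell)

geom <- grid_geometry(340, 1 / 5)
dist <- size_distribution(mean_nx = 10, mean_ny = 30, sigma_log = 0.25,
                          n_crystals = 200, seed = 1)
pat  <- simulate_merged(atoms, cell, dist, geom)

refl <- enumerate_reflections(cell, 5, quadrant_only = TRUE, domain = "square")
fit  <- refine(pat, refl, initial_peak_params(cell, 10, 30),
               fit_config(max_cycles = 10, cost_rel_tol = 1e-5))
fit
#> <fit_result> 240 reflections, 2 cycle(s) (converged)
#>   R_p = 0.7067, R_wp = 0.929, cond(P) = 1.0613
#> <peak_params> eta = (0.5142, 0.8337); Gamma_G = (0.0008068, 0.0003073), Gamma_L = (0.03677, 0.001568) 1/A

ref   <- reference_structure_factors(atoms, cell, fit$reflections)
sweep <- radius_sweep(pat, ref, fit)
print(sweep[c(1, 5, 9, 13, 17), ], digits = 3, row.names = FALSE)
#>  radius int_error wpf_error n_included n_excluded
#> 0.00000     0.777     0.347        228         12
#> 0.00156     0.590     0.347        228         12
#> 0.00313     0.557     0.347        228         12
#> 0.00469     0.557     0.347        228         12
#> 0.00625     0.566     0.347        228         12
```

The fit used 240 symmetry-unique reflections (one per 4/m orbit); the
overlap system is well conditioned (cond(P) ≈ 1.06, near 1 means peaks
untangle cleanly). The sweep rows show the mean relative error of
integration-extracted moduli |F| against the reference as the circular
integration radius grows from 0 (nearest pixel) to the Wigner–Seitz
boundary a*/2 ≈ 0.00625 Å⁻¹: on this coarse grid (≈10.6 pixels between
Bragg positions) integration is off by 56–78% wherever the mask is drawn,
while whole-pattern fitting holds a radius-independent 35% (the large
`R_p`/`R_wp` reflect the sub-pixel interference spikes the smooth profile
cannot reproduce; the moduli come from the peak-untangling solve, not from
the residual). The 12 excluded reflections are the fixed weak set (reference
modulus below 10% of the median). High-level drivers (`cmd_simulate()`,
`cmd_fit()`, `cmd_compare()`, `cmd_overlap()`) run the same pipeline from a
YAML config, and `inst/cli/wpfx.R` exposes them as a command line.

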