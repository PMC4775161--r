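---
title: "Whole-pattern fitting of merged nanocrystal diffraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-pattern fitting of merged nanocrystal diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpfx)
```

## The problem

Serial femtosecond crystallography (SFX) merges diffraction snapshots from
thousands of nanocrystals of varying size into a single data set. For
crystals only tens of unit cells across, the finite-lattice interference
function broadens every Bragg reflection and fills the inter-Bragg regions
with scattering, so the reflections are no longer isolated: the intensity
anywhere in the merged pattern is a collective contribution of many peaks.
Integration-style extraction (summing pixels inside a mask around each
Bragg position) then mixes neighbouring tails into every integral, and its
accuracy depends on the mask size.

wpfx treats the merged pattern instead as a continuous function of the
scattering vector and fits it whole, the way Le Bail decomposition fits 1D
powder patterns, extended here to 2D reciprocal-lattice planes. The package
contains the three pieces needed to study this quantitatively end to end:

1. a finite-lattice diffraction simulator for ensembles of needle
   nanocrystals in the (hk0) plane (`simulate_merged()`),
2. the whole-pattern fitting engine (`refine()`), and
3. the competing integration extractor and accuracy analytics
   (`integrate_peaks()`, `radius_sweep()`, `overlap_decomposition()`).

## Model

Throughout, the scattering-vector convention is $|q| = 1/d$, so reflection
$(h, k, 0)$ of a tetragonal cell sits at $q_k = (h/a, k/b)$ in
Å$^{-1}$, and the reciprocal-cell edge is $a^* = 1/a$.

**Simulated data.** A crystal of $N_X \times N_Y$ whole unit cells scatters

$$ I(\mathbf q) = |F(\mathbf q)|^2 \, L_{N_X}(q_x a)\, L_{N_Y}(q_y b),
\qquad L_N(t) = \frac{\sin^2(\pi N t)}{\sin^2(\pi t)}, $$

where $F(\mathbf q)$ is the continuous unit-cell transform computed from
point scatterers with isotropic Debye–Waller factors
($\exp(-B|q|^2/4)$ on the amplitude under this convention). The merged
pattern is the equal-weight sum over an ensemble whose $N_X$, $N_Y$ are
drawn from independent log-normal distributions parameterized by their
means. The second, cross-term part of the exact finite-crystal intensity
(the one that carries inter-Bragg phase information) is deliberately not
modelled; only the first summation is simulated and fitted.

**Fitted model.** The merged intensity is modelled as

$$ I_{\mathrm{calc}}(\mathbf q) = \sum_k |F_k|^2\, \Phi_k(\mathbf q -
\mathbf q_k), $$

with one profile $\Phi$ shared by all reflections: a separable product of
two one-dimensional normalized pseudo-Voigt functions, one per reciprocal
axis. That gives six adjustable parameters — mixing weights
$\eta_x, \eta_y \in [0,1]$ and FWHM widths $\Gamma_{G,x}, \Gamma_{L,x},
\Gamma_{G,y}, \Gamma_{L,y}$ in Å$^{-1}$ — matching the anisotropic
broadening of needle crystals with independent size statistics along the
two axes. A linear dependence of each width on the peak's $|q|$ is
available (`slopes` in `peak_params()`) but off by default: defect-free
ensembles are fitted with a single common parameter set.

**Refinement.** Fitting alternates the two Le Bail ingredients:

- *moduli re-estimation*: the observed peak intensities $I_j$ (read from
  the merged grid at the exact Bragg positions) are untangled through the
  linear system $\mathbf I = \mathbf P\, \mathbf F$, where
  $P_{ji} = \Phi_i(\mathbf q_j - \mathbf q_i)$ collects the profile
  cross-contributions; the system is solved by Gaussian elimination with
  partial pivoting, and its conditioning is monitored by the singular-value
  ratio (`condition_number()`);
- *profile refinement*: the error cost
  $\Psi = \sum_i w_i (I_{\mathrm{obs},i} - I_{\mathrm{calc},i})^2$ over
  **all** pixels of the pattern is minimised over the six profile
  parameters.

Fit quality is monitored by the standard profile residuals $R_p$ and
$R_{wp}$. Extracted moduli are placed on an absolute scale by a Wilson fit
of a scale factor $k$ and overall thermal parameter $B$ against reference
moduli (`wilson_fit()`), exactly as the integrated intensities are.

## Numerical design choices

Several choices are open in the classical formulation; wpfx resolves them
as follows, and the test suite pins the resulting behaviour.

**Grid-consistent peak reads.** Bragg positions rarely coincide with pixel
centers, so the observed peak intensity is a bilinear interpolation of the
grid at $\mathbf q_j$. For the linear system to be consistent, `refine()`
by default evaluates each $P_{ji}$ through the *same* bilinear stencil
(`p_mode = "interpolated"`): model and data are probed with the identical
linear functional. This makes data generated exactly by the model
recoverable to machine precision regardless of how the grid is registered
against the lattice — with analytic evaluation the interpolation bias
alone puts a floor of several tenths of a percent under the recovered
moduli. The exported `build_P()` keeps the analytic convention
($\Phi_i$ at the exact offset), which is also what the reported condition
number refers to; the condition of the sampling-consistent system actually
solved is reported separately (`cond_solve`) because it reflects grid
registration of sub-pixel peaks rather than genuine profile overlap.

**Variable projection.** Alternating *strictly* — refine shapes at fixed
moduli, then re-solve moduli — has spurious fixed points: the solved moduli
reproduce the observed peak reads for any trial shapes, so the fixed-moduli
cost loses the coupling between shapes and moduli. `refine()` therefore
folds the moduli re-estimation into every parameter evaluation (each trial
shape is scored together with the moduli it implies), which is the same
alternation with the linear solve concentrated out. The search is
non-monotone with best-state memory; the reported cost trace is the running
best and never increases. Convergence is declared when the relative cost
improvement falls below `cost_rel_tol` (default $10^{-6}$) or after
`max_cycles` (default 50).

**Optimizer.** The default is bounded least squares (Levenberg–Marquardt on
the full pixel residual vector, through an unconstrained reparameterisation:
logit for the mixing weights, log for the widths). A Nelder–Mead simplex
option is provided; it is slower and, on merged Laue data, occasionally
settles in a different local minimum.

**Symmetry.** Laue class 4/m is handled by fitting one representative per
orbit (canonically $h \ge 1$, $k \ge 0$); the model is always evaluated
over the symmetry-expanded plane, and the P system ties orbit members to
one unknown by summing their columns, so tails of out-of-quadrant mates
still contribute near quadrant boundaries. 4/mmm is deliberately *not*
assumed: $(k, h)$ is not treated as equivalent to $(h, k)$.

**Degenerate cases.** Negative solved moduli (possible for weak reflections
swamped by neighbours) are clamped to zero once, with a warning, and the
system is not re-solved. Reflections outside the grid are excluded with a
warning. A pivot below tolerance raises a singular-system error carrying a
condition estimate. The Wilson fit refuses designs with fewer than three
usable reflections or a single resolution shell.

**Overlap analysis.** `overlap_decomposition()` splits the fitted model
around one reflection into its own-peak and neighbour terms on circles of
increasing radius, keeping sample points whose model intensity exceeds 2%
of the reflection's peak intensity. The peak-intensity reference defaults
to the analytic model maximum; the drivers pass the *observed* peak
intensity (the same quantity that enters the linear system), which anchors
the floor in the merged data. The distinction matters on coarse grids: the
analytic maximum of a fitted profile with a sharp Gaussian core can sit an
order of magnitude above any observed pixel, which truncates the radial
analysis long before the Wigner–Seitz boundary.

## What the simulator emulates — and what it does not

`simulate_merged()` reproduces the idealised study conditions: whole unit
cells only, a fixed needle orientation (lattice axes along the grid axes),
equal per-crystal weights, no photon noise, no background, no lattice
disorder, no partial unit cells on crystal surfaces, no detector geometry
corrections. Real merged SFX data violate all of these to some degree, so
passing tests demonstrate correctness of the method under the model's own
assumptions, not performance on experimental data.

Intensities are evaluated at pixel *centers* by default. A merged ensemble
of 30–60-cell crystals has a central interference maximum well under a
pixel wide on practical grids, and a point sample of such a spike depends
strongly on where the lattice falls relative to the pixel grid. This
registration sensitivity is physical to the sampling model, and it is
exactly what degrades integration-based extraction on coarse grids while
whole-pattern fitting remains stable — the effect the reduced-scale
comparison exercises. It also, however, penalises integration *more for
larger crystals* (sharper spikes), which inverts the expected
size trend: detectors integrate over the pixel area rather than sampling
its center. For analyses where that distinction matters, the simulator
accepts `oversample = k` to average the separable Laue factors over $k$
sub-offsets per pixel, emulating a detector pixel; the size-trend
acceptance check runs at the full study scale (1024² grid, 2000 crystals)
with `oversample = 3`, while all other checks use plain center sampling.

## Study conditions and problem sizes

The packaged analyses use a langerin-like tetragonal cell
($a = b = 79.959$ Å, $c = 90.419$ Å) with a synthetic test cell of 40
four-fold-symmetrised point scatterers standing in for the deposited
structure — fixtures must not require external coordinate files, and the
extraction method is agnostic to form-factor detail. For real PDB input,
`read_pdb_cell()` honours occupancies and B factors and
`expand_form_factors()` switches on tabulated four-Gaussian form factors
(each Gaussian term is exactly a Debye–Waller increment under this q
convention, so expanded atoms flow through the unchanged point-scatterer
transform).

Ensembles default to $\langle N_X \rangle = 10$ unit cells across the
needle and $\langle N_Y \rangle$ between 30 and 60 along it, with
log-normal `sigma_log = 0.25`: the study design fixes only the means, and 0.25
gives a visible size spread without pathological tails. The routine test
scale is a 340×340 grid to 5 Å with 200 crystals (about 10.6 pixels
between Bragg positions — the coarse-grid regime), which keeps a full
simulate–fit–sweep cycle in the tens of seconds; the size-trend comparison
uses the full 1024² / 2000-crystal conditions. Weak reflections — those
whose reference modulus falls below 10% of the median — are excluded from
mean relative errors, as is conventional, and the threshold is
configurable.

## Limitations

- 2D planes only; no 3D merged volumes.
- No refinement of unit-cell parameters or per-peak positions; Bragg
  positions are computed from the cell.
- One common profile for all reflections (no partial profile relaxation
  for weak reflections), with at most a linear $|q|$ dependence of the
  widths.
- The inter-Bragg cross term of the exact finite-crystal intensity is
  neither simulated nor exploited; no direct phasing.
- The integration comparator implements circular masks with a
  center-in-circle pixel rule; Wigner–Seitz-shaped or rectangular masks
  and local background subtraction are not implemented.
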