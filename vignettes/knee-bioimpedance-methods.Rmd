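---
title: "Methods: personalized knee bioimpedance modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized knee bioimpedance modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneebis)
```

## The model

`kneebis` predicts the tetrapolar impedance-magnitude spectrum of a human
knee between 1 and 49 kHz and inverts that prediction against a measured
spectrum to recover subject-specific tissue parameters. Three layers of
modelling are stacked:

1. **Tissue dielectrics.** Every tissue is a multi-dispersion Cole--Cole
   medium,
   $$\dot\varepsilon_{eff}(\omega) = \varepsilon_\infty +
     \sum_{n=1}^{4}\frac{\Delta\varepsilon_n}{1+(j\omega\tau_n)^{1-\alpha_n}}
     + \frac{\sigma_{dc}}{j\omega\varepsilon_0},$$
   under the $e^{+j\omega t}$ convention, so the conduction term carries
   negative imaginary permittivity and the equivalent conductivity
   $\sigma_{eq}=-\omega\varepsilon_0\,\mathrm{Im}\,\dot\varepsilon_{eff}$ is
   non-negative and non-decreasing in frequency. The packaged table
   (`default_tissue_table()`) covers dry skin, wet skin, subcutaneous fat,
   bone, and skeletal muscle both transversal and parallel to the fibers.
   Relaxation times are converted from the source table's mixed units
   (ps/ns/us/ms per dispersion column) to seconds at definition time, and
   empty cells are represented as absent dispersions rather than zero
   increments, so every stored $\tau$ is strictly positive. Skeletal muscle
   is anisotropic: the scalar permittivity becomes a diagonal tensor in the
   fiber frame (`muscle_tensor()`), with fibers along the limb axis by
   default.

2. **Geometry.** The knee is five concentric layers around a cylindrical
   bone core: dry skin (stratum corneum + lucidum, fixed at 60 um), wet skin
   (deeper epidermis + dermis; 4.501 mm male / 3.666 mm female),
   subcutaneous fat (from BMI via the linear relation
   $BMI = 0.385\,SFT + 16.991$, SFT in mm), muscle, and bone (25.640 mm male
   / 22.760 mm female core radius). The outer radius is the mean of three
   knee circumferences divided by $2\pi$, and the muscle layer is the
   *residual* closing that radius exactly, so thickness conservation holds
   by construction. Two open points were settled as follows:

   * The linear fat relation is sex-blind, yet the anchored per-sex
     reference case differs by sex. The default "calibrated" mode multiplies
     the raw inversion by per-sex factors (0.97336 male, 1.08734 female)
     chosen once so the reference case (BMI 23, radius 65 mm) is reproduced;
     `calibrated = FALSE` restores the raw relation.
   * The reference table's own muscle-layer entries are inconsistent with
     the residual rule (its five thicknesses do not sum to the stated
     radius). The residual rule is implemented; the table's muscle values
     are not reproducible and are not used.

   The relation is undefined below BMI $\approx 17$ (non-positive fat
   thickness) and a profile whose fixed layers exceed the outer radius is
   rejected as geometrically infeasible, with the deficit reported.

3. **Field problem.** In the electric quasi-stationary limit the complex
   potential solves $\nabla\cdot(\dot\sigma\nabla\bar\varphi)=0$ with the
   single coefficient $\dot\sigma = j\omega\varepsilon_0\dot\varepsilon_{eff}$
   per region (tensor-valued in muscle: transversal in-plane, parallel
   axially). The divergence form enforces continuity of normal current
   density across tissue interfaces naturally. Drive electrodes are ideal
   equipotential patches held at $\pm V/2$; the remaining skin is insulated;
   no external current density is applied.

## The forward solvers

Three forward models share one interface (`knee_model()`):

* **Layered surrogate** (`analytic_layered_impedance()`): the series sum
  $Z(\omega)=\sum_i d_i/(\dot\sigma_i(\omega)A)$ over the five layers with a
  current-tube cross-section $A$ equal to the drive-patch area (20 x 20 mm by
  default). The muscle layer uses the *parallel* parameter set: in a
  tetrapolar measurement the dominant muscle path runs axially, along the
  fibers. This surrogate is mesh-free and evaluates in microseconds, which
  is what makes fitting (hundreds of forward solves) and cohort-scale
  validation cheap; it is also the analytic oracle for the layered
  finite-element tests.
* **2D FEM** (`fem-2d`): first-order triangles on a structured polar mesh of
  the cross-section, per-unit-length physics, divided by the electrode
  height to report Ohms. Fast enough for property tests and refinement
  studies.
* **3D FEM** (`fem-3d`): the cross-section extruded along the limb axis;
  prisms are split into tetrahedra with the smallest-global-index rule so
  neighbouring prisms tetrahedralize conformally.

Numerical choices that matter:

* **Meshing the 60 um skin.** Layer interfaces are always mesh circles and
  the dry-skin ring keeps a dedicated radial division at every resolution,
  so the dominant numerical hazard (a layer four orders of magnitude thinner
  than the domain) is resolved by construction, at high element aspect
  ratio. The highly resistive ring also mollifies the patch-edge current
  singularity, acting like a distributed contact impedance.
* **Electrode-conforming grids.** Patch edges are weak singularities of the
  potential. The angular (and axial, in 3D) grid contains the exact patch
  edge coordinates and is graded geometrically toward them. Without this the
  effective patch extent jumps between resolutions and the impedance does
  not converge below the percent level; with it, the 10 kHz reading changes
  by about 0.01% between the second and third default refinement levels.
* **Electrode model.** All four patches are ideal equipotential conductors:
  drive patches are Dirichlet-merged DOFs, sense patches float as merged
  DOFs with zero net current (their "patch average" is their common
  potential). This realizes the zero-current sense condition exactly and
  makes discrete reciprocity hold to solver precision, because the
  four-terminal admittance matrix inherits the symmetry of the complex
  stiffness matrix. No electrode--skin contact impedance is modelled.
* **Linear algebra.** The complex symmetric system $K = K_r + jK_i$ has
  positive semidefinite $K_r$ (conduction losses) and $K_i$ (displacement),
  so $M = K_r + K_i$ is SPD. One CHOLMOD factorization of $M$ preconditions
  an unrestarted GMRES whose operator spectrum lies on the arc
  $(1+jt)/(1+t)$, $t \ge 0$ --- bounded away from the origin for any passive
  tissue table --- giving convergence in a few tens of iterations at
  relative residual $10^{-11}$, with a direct block-real solve as fallback.
* **Terminal currents** are the algebraic residuals of the merged electrode
  DOFs (the discretely consistent flux), so charge conservation is exact and
  the volume power balance $\sum_t \mathrm{Re}(V_t I_t^{*}) =
  \int\sigma_{eq}|\nabla\varphi|^2$ is an independent cross-check used in
  the tests.
* **Frequency grid.** Thirteen points, logarithmically spaced over
  [1, 49] kHz (the spacing is not prescribed by the measurement protocol;
  log spacing matches the dispersive physics), with the band edges exact.

A note on spectral shape: the *bipolar* magnitude falls monotonically with
frequency as every tissue's conductivity rises, but the *tetrapolar
transfer* magnitude may pass through a minimum inside the band (observed
near 10--25 kHz on the reference geometry) as displacement currents reroute
the current paths between drive and sense. The tests therefore assert
monotone decrease only through the lower half of the band, plus passivity
($\mathrm{Re}\,Z > 0$) everywhere.

## Anisotropic muscle identification

Only transversal muscle parameters are tabulated in the literature; the
parallel set is identified from a reference permittivity/conductivity
spectrum under the requirement of staying close to the transversal anchor:
minimize $\|s(x_L) - s(x_P)\|_2$ subject to the model spectrum matching the
reference. Choices:

* **Scaling $s(\cdot)$:** $\Delta\varepsilon$, $\tau$ and $\sigma_{dc}$ in
  $\log_{10}$; $\alpha$ and $\varepsilon_\infty$ linear. The parameters span
  seven decades; an unscaled norm would be meaningless.
* **Constraint relaxation:** the complex equality over all sampled
  frequencies cannot hold exactly for finite parameters. It is relaxed to a
  relative misfit tolerance (default $10^{-4}$) and solved as a penalized
  program, $\|s(x_L)-s(x_P)\|^2 + \lambda\,\mathrm{misfit}^2$, with
  $\lambda$-continuation ($\times 10$ per step from 10) under
  box-constrained quasi-Newton (L-BFGS-B) in the scaled space. If the
  tolerance is unreachable the best-effort result is returned with a
  `feasible = FALSE` flag rather than an error.
* **Misfit definition:** root-mean-square of per-frequency *relative* errors
  averaged over the two channels (real permittivity, equivalent
  conductivity). Channel values span seven decades across the grid; a
  norm-ratio misfit would see only the largest low-frequency values, making
  high-frequency dispersions invisible. A model uniformly 10% off scores
  exactly 0.10 under either reading.
* **Tie-breaks:** when distinct parameter vectors fit equally well (e.g.
  two dispersions sharing $\tau$ and $\alpha$, where only the summed
  increment is observable), the distance term selects the solution closest
  to the anchor --- this anchor-pull is a tested property, not an accident.
* The reference muscle data themselves are not redistributable, so the
  package ships a synthetic generator (`generate_reference_muscle_spectra()`,
  48 log-spaced points over 1 Hz--1 GHz by default) and the identified
  parallel row in the default table is the canonical output of this
  procedure. Parameters whose relaxation lies far above the sampled band
  (the picosecond dispersion) are only weakly identified and are pinned
  near the anchor by the distance term --- the round-trip tests assert
  recovery accordingly.

## Personalization

Seven parameters drive the subject customization: wet-skin
$\Delta\varepsilon_3$, $\Delta\varepsilon_4$; fat $\alpha_4$, $\sigma_{dc}$;
parallel-muscle $\alpha_3$, $\tau_4$, $\sigma_{dc}$. The reconstruction
error is the relative $L_2$ distance of magnitude spectra on the shared grid
(no interpolation; mismatched grids are an error), and the fit minimizes it
by Nelder--Mead in a transformed space: natural log for increments,
relaxation times and conductivities, a bounded logit on
$(10^{-4},\,0.95)$ for the broadening exponents. Bounds are enforced by the
transform, never by rejection, so the simplex stays well-defined.
Magnitude-only fitting is deliberate: the instrument reports magnitude
spectra, and phase, when present in a file, is ignored by the objective.

Two departures from a plain simplex, both deterministic:

* after the first Nelder--Mead pass (cap 500 iterations, relative objective
  tolerance $10^{-10}$) the simplex is restarted once from the best point;
* a Levenberg--Marquardt least-squares polish then refines the optimum, and
  is accepted only if it does not increase the error. The reason is
  conditioning: on the 13-point band the seven-parameter Jacobian has a
  condition number of order $10^5$ --- the parallel-muscle $\alpha_3$,
  $\tau_4$ and $\sigma_{dc}$ act on nearly coincident relaxation corners
  (both near 220 Hz) and trade off almost freely. A simplex alone stalls on
  the flat valley with parameter errors around 10% even at
  $\varepsilon_{fit}\sim 10^{-6}$; the Gauss--Newton steps of LM walk the
  valley to the least-squares optimum, after which noise-free recovery of a
  uniformly perturbed truth is at the percent level.

Fitting never returns a point worse than its start (monotone acceptance),
and identical inputs give bit-identical results --- there is no hidden
randomness anywhere in the fit. The one-at-a-time `sensitivity_analysis()`
scores any tissue parameter by the relative spectral change under a 10%
step (zero-valued parameters score zero under a relative step; an $\alpha$
stepped past 1 is clipped with a warning) and ranks them; with the layered
surrogate the full ~76-parameter probe costs one forward solve each.

## The synthetic cohort

`generate_cohort()` emulates the validation study's population: Bernoulli
sexes (27% male), BMI from a truncated normal $25 \pm 4$ kg/m$^2$, knee
circumference $39 \pm 4$ cm with the three per-subject measurements
jittered uniformly within $\pm 1$ cm, one third of subjects osteoarthritic.
Each subject's dielectric truth perturbs the seven defaults independently
and log-uniformly within $\times[0.5, 2]$ (osteoarthritic: $\times[0.33,
3]$, wider but otherwise identical, consistent with pathology not changing
the spectral trend), clipped to the parameter bounds. Measured spectra are
the surrogate forward model plus multiplicative Gaussian noise on $|Z|$
(default 3%, floored at 10% of the clean value) --- bioimpedance noise
scales with magnitude, and no instrument noise figure is published for the
band. Every stochastic operation takes an explicit seed and restores the
caller's RNG state.

What the generator does *not* emulate: real measured spectra (electrode
placement error, cable and contact parasitics, inter-subject anatomy beyond
the five-layer abstraction), edema (excluded by design), and age or skin
condition effects. Two systematic consequences are worth knowing. First,
because truths are drawn from the surrogate's own parameter space, fitted
errors on the synthetic cohort reflect noise and optimizer quality, not
model misspecification --- passing the cohort test shows the inverse
machinery works, not that a real knee is a five-layer cylinder. Second,
geometric feasibility (a thin knee cannot host a high-BMI fat layer, and
the fat relation needs BMI > 17) redraws some subjects, truncating the
accepted BMI distribution: under the study conditions its mean shifts down
by roughly one unit and its spread shrinks below the nominal 4. The tests
assert clean sampling-theory agreement in a configuration where no
truncation binds, and the direction and rough size of these biases under
the study conditions.

## Problem sizes and budgets

The package's own test and validation runs use: 2D meshes at resolution
levels 1--3 (about 1.5k--8.5k nodes), a single 3D reference mesh (about 20k
nodes, solved in a couple of seconds per frequency), identification on
48-point reference grids, and a 30-subject surrogate-fitted cohort (about
two seconds per subject fit). These sizes were chosen so the whole suite
runs on a laptop-class single core in a few minutes while keeping every
numerical check comfortably inside its tolerance.

## Known limitations

* The bone core is a cylinder; patella/condyle shapes, knee flexion and
  per-substratum skin structure are out of scope.
* No electrode--skin contact impedance; electrodes are ideal conductors.
* Magnitude-only objective: phase information, where an instrument provides
  it, is unused.
* The identifiability of the parallel-muscle triplet on the 13-point band
  is marginal by construction (see the conditioning discussion): reported
  per-parameter values from a single noisy spectrum should be read with
  that in mind even when $\varepsilon_{fit}$ is small.
* Validity is restricted to [1 Hz, 1 GHz] for the dielectrics and to the
  quasi-static regime for the field problem; inductive and propagative
  effects are neglected throughout.
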