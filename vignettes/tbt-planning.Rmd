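---
title: "Planning simultaneous interstitial hyperthermia and HDR brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning simultaneous interstitial hyperthermia and HDR brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tbtplan)
```

## The planning problem

ThermoBrachyTherapy (TBT) delivers high-dose-rate brachytherapy (HDR-BT) and
capacitively coupled 27 MHz interstitial hyperthermia simultaneously, through
dual-function applicators: needle-shaped catheters that guide the stepping
radiation source and carry two 20 mm cylindrical electrodes separated by a
5 mm gap.  Heating during irradiation radiosensitizes tissue, so a heated
voxel receiving physical dose $D$ at temperature $T$ experiences the cell
kill of a larger radiation-only dose.  The planning question this package
answers is: given a physical HDR-BT dose distribution (possibly scaled
down), which electrode amplitudes make the *combined* treatment meet the
radiotherapeutic protocol, while sparing the organs at risk (OAR: urethra,
rectum, bladder) and keeping tissue below a temperature ceiling?

The pipeline has five stages, each an exported module:

1. **tissue model** — a voxelized anatomy with per-tissue electric and
   thermal properties, and the applicator geometry.  A synthetic pelvic
   phantom generator stands in for CT segmentation so the whole chain is
   testable without clinical data.
2. **electromagnetic solver** — the electroquasistatic potential
   $\nabla\!\cdot\!\big((\sigma + j2\pi f\varepsilon)\nabla V_i\big) = 0$
   per electrode $i$, giving fields $\mathbf E_i = -\nabla V_i$ and
   unit-amplitude power densities $P_i = \tfrac{\sigma}{2}|\mathbf E_i|^2$.
3. **bioheat solver** — the steady-state Pennes equation for the
   temperature elevation of each unit power field, and their superposition
   $T = T_b + \sum_i v_i^2\,\Delta T_i$ for amplitudes $v$.
4. **radiobiology** — the temperature-dependent linear-quadratic (TDLQ)
   model converting $(D, T)$ into an equivalent physical dose.
5. **optimizer** — a penalized objective over dose-volume metrics of the
   equivalent dose, minimized over the amplitude box by particle-swarm
   search with a deterministic physics-based warm start.

## Models and assumptions

### Electroquasistatics

At 27 MHz the wavelength in tissue is metres while the domain is
centimetres, so a quasistatic scalar-potential model is appropriate.  The
solver is a flux-conservative finite-difference scheme on the voxel grid
with harmonic-mean face admittances, solved matrix-free by a
Jacobi-preconditioned conjugate orthogonal CG (plain CG in the real limit)
to a relative residual of $10^{-8}$.

Boundary conditions per electrode solve: the active electrode's voxels at
1 V, **all other electrode voxels and the outer boundary grounded**.
Grounding the inactive electrodes is the only convention under which the
per-electrode fields superpose exactly to the simultaneous-drive field
($\mathbf E_{tot} = \sum_i v_i \mathbf E_i$), and it is physically the
zero-amplitude state of a driven channel.  The thin Parylene C coating of
the electrodes is far below voxel resolution, so it enters as a sheet
admittance in series with each electrode-tissue face; with harmonic-mean
averaging this is exact if the electrode cell is assigned
$a_\text{eff} = \tfrac{h}{2}\,(\sigma_c + j2\pi f\varepsilon_0
\varepsilon_{r,c})/t_c$ for coating thickness $t_c$ (default 20 µm, a
typical conformal Parylene C layer) and cell size $h$.  In practice the
tissue spreading impedance dominates, so the coating is a small correction.

### Steady-state bioheat

All reported quantities concern the steady temperature distribution of a
one-hour exposure, so the transient term is dropped.  Solving for the
elevation $\Delta T = T - T_b$ above the 37 °C equilibrium cancels the
metabolic heat term.  The perfusion sink
$\rho_b c_b \rho\,\omega\,\Delta T$ uses constant, tissue-specific
perfusion; blood parameters default to $\rho_b = 1050$ kg/m³,
$c_b = 3617$ J/kg/K.  The boundary is Dirichlet at baseline, and internal
air (the rectal lumen) is excluded from the conduction stencil so no heat
flows through it.  The prostate's high perfusion (394 ml/kg/min) gives a
thermal penetration depth of ≈4.4 mm, which is what makes per-electrode
heating patterns local.

### Temperature superposition and its limits

The optimizer evaluates $T = T_b + \sum_i v_i^2 \Delta T_i$, a weighted sum
of precomputed fields — thousands of times cheaper than a coupled solve.
This drops the interference (cross) terms of the power quadratic form.  The
package quantifies that approximation with a 3D gamma-index comparison
(5 % of the maximum reference *elevation*, 0.5 mm distance-to-agreement,
trilinear sub-voxel sampling, analysis region above 10 % of the maximum
elevation) between the superposed temperature and a single coupled bioheat
solve of the total power including all cross terms.

The approximation is *regime-dependent*, and the package is explicit about
this: when many neighbouring electrodes are driven coherently at comparable
amplitudes, mutual shielding makes the coupled field much weaker than the
superposed estimate and the gamma criterion fails badly.  Optimized
interstitial plans do not operate there — they heat sparsely, through a few
strongly driven, spatially staggered channels, leaving most of the gland
below 39 °C.  The bundled validation draw (`validation_amplitudes()`)
therefore activates a small number of mutually distant channels (default
4 of 36) with seeded random amplitudes scaled to a 45 °C peak; in that
regime the passing rate is 98–100 % across seeds, with residual misses in
the far field where elevations are small, and simulated OAR (rectum)
temperatures should be treated with more caution than target temperatures.

### Brachytherapy dose and the surrogate planner

Doses come from a TG-43-style point-source kernel (inverse square with a
configurable radial dose polynomial and constant anisotropy; near-field
capped at half a voxel diagonal).  Since no clinical dwell times exist for
a synthetic phantom, a surrogate planner fits nonnegative dwell weights by
NNLS to the prescription at prostate-surface points plus urethra-surface
control points, then rescales uniformly so the coverage objective
($V_{100\%} \ge 95\%$ of the prostate at $D_p = 13.5$ Gy) holds exactly at
the order statistic.  The surrogate meets the coverage objective and the
rectum/bladder criteria on the default phantom but is more heterogeneous
than a clinical plan (higher $V_{150\%}$, urethra $D_{0.1cc}$ ≈ 1.25
$D_p$); the protocol report states exactly which criteria it misses.  The
TBT workflow equally accepts an imported external dose grid on the model
raster.

### TDLQ equivalent dose

Radiosensitization scales the LQ coefficients exponentially between 37 °C
and the reference temperature $T_{ref} = 43$ °C:
$\alpha(T)/\alpha_{37} = r^{(T-37)/(T_{ref}-37)}$ with
$r = \alpha(T_{ref})/\alpha(37)$, likewise for $\beta$; the same law
extrapolates above $T_{ref}$, bounded in practice by the 47.5 °C ceiling.
The equivalent physical dose normalized to the physical dose is

$$EQD_{phys} = \frac{\alpha/\beta \cdot r_\alpha(T)\,D + r_\beta(T)\,D^2}
{\alpha/\beta + D},$$

which equals $D$ exactly at 37 °C and for the no-sensitization (`NONE`)
preset.  Bundled presets: PC-3 (2.4, 6.8), DU-145 (0.8, 1.8), their mean
(1.6, 4.3), all at $\alpha/\beta = 3$ Gy.  Absolute $\alpha_{37}$,
$\beta_{37}$ never enter the planning pipeline — only their ratio does —
so `survival_fraction()` requires them explicitly and is provided for
completeness.  Because normal-tissue sensitization data do not exist, OAR
equivalent doses are evaluated under two bracketing assumptions, both
first-class modes: sensitization equal to tumor (worst case, used during
optimization) and none at all (best case, in which the OAR equivalent dose
is simply the scaled physical dose).

### Objective and optimizer

The plan objective is $\Omega = W\sum_i PF_i + \sum_j SF_j$ with penalty
$PF_i = \max(0, p_i(C_i - L_i))$ for each constraint (coverage high-pass at
the BT-only plan's $V_{100\%}$; urethra $D_{0.1cc}$, rectum and bladder
$D_{1cc}$ low-pass at their BT-only values; $T_{max} \le 47.5$ °C low-pass
over all tissue) and scores $SF_j = w_j(O_j - G_j)$ (urethra $D_{0.1cc}$
and rectum $D_{1cc}$ toward 0 with weight 1, prostate $V_{150\%}$ toward
30 % with weight 0.01).  The score sign is chosen so that lower is better
under minimization, consistent with the stated intent of the scoring
functions.  $W = 10^3$ makes any constraint violation dominate.

Amplitudes live in $[0, v_{max,i}]$ with $v_{max,i}$ calibrated so a single
electrode at full drive just reaches the ceiling locally.  The search is a
standard global-best PSO (inertia 0.7298, cognitive = social = 1.49618,
velocity clamped to 20 % of the range, positions clipped to bounds, seeded
and bit-reproducible).  Two aids make the search reliable in 36 dimensions:

* a **warm start** that inverts the TDLQ relation voxel-wise for the
  elevation each underdosed prostate voxel needs, drops the hardest voxels
  the coverage limit allows to stay cold, and solves an NNLS system for
  $v^2$ against the elevation basis; the swarm is seeded with this point
  and scaled variants of it;
* a **continuous search surrogate** for the stepwise $V_{100\%}$ penalty —
  the shortfall of the equivalent dose at the coverage order statistic
  below $D_p$ — which vanishes exactly where the constraint holds, so the
  reported objective is untouched; a bounded Nelder-Mead polish then
  refines the swarm optimum.

Metric evaluation is restricted to the organ masks plus a heating envelope:
the voxels whose elevation could exceed 0.2 K under the amplitude bounds
(since elevations are nonnegative and monotone in the amplitudes, the
ceiling cannot bind outside that envelope by more than 0.2 K).

## The synthetic phantom

The default phantom is the package's study condition: a 96 mm cube at
1.5 mm isotropic resolution holding a ≈35 cc ellipsoidal prostate with a
coaxial 3 mm urethra, a posterior rectum (10 mm wall radius, air lumen), a
superior bladder sphere, muscle background with a peripheral fat shell, and
18 applicators (36 electrodes) placed on a 5 mm perineal template by
farthest-point selection with seeded jitter, snapped to the voxel lattice
so each catheter axis passes through voxel centres (which guarantees a
nonempty 1 mm-radius rasterization at 1.5 mm spacing).  Dwell positions
run along each track inside the prostate at 2.5 mm steps.

What it emulates: organ topology and size, implant density and electrode
layout, tissue contrasts in conductivity, perfusion and thermal
conductivity, and protocol-realistic BT dose shapes.  What it does not:
patient-specific anatomy variation, segmentation noise, curved needle
tracks, intra-gland heterogeneity, rectal-wall cooling, and clinical dwell
optimization.  Passing tests on the phantom therefore validate the
*machinery* (solvers, superposition, radiobiology, optimization), not
patient-level dosimetry; the published patient-cohort statistics are
intentionally out of scope.

## Numerical choices

* PDE solves: relative residual $10^{-8}$, matrix-free stencil in C++;
  air voxels are excluded (insulating) in the thermal solve.
* Gamma analysis: global normalization to the maximum reference elevation;
  sub-voxel sampling step `spacing/3` when the spacing is coarser than the
  DTA; search radius 3 × DTA; pass condition $\gamma \le 1 + 10^{-9}$ so
  points exactly on the criterion surface count as passing.
* Hot-volume metrics ($D_{xcc}$, $T_{10/50/90}$): descending sort with
  linear interpolation on cumulative volume; ties use the ≥ convention.
* Default study sizes were chosen once for desk-scale reproducibility:
  64³ voxels, 36 electrode solves per basis, PSO with 40 particles ×
  ≤250 iterations plus ≤3000 polish evaluations for the bundled studies
  (the spec-level defaults of 50 × 300 remain the function defaults).
* Seeds: every stochastic step (phantom jitter, validation draw, swarm)
  takes an explicit integer seed and restores the caller's RNG state.

## Known limitations

* The superposition validation, and hence the optimizer's temperature
  model, is only accurate for sparse coherent drive patterns (see above);
  an all-channels-on coherent drive is outside the validated regime.
* The surrogate BT planner does not enforce the urethra hard constraint the
  way clinical inverse planning does; its report makes the misses explicit.
* Point-source TG-43 without tabulated anisotropy under-models the dose
  along the applicator axis.
* Constant perfusion ignores thermoregulation; rectal cooling devices are
  not modelled.
* The extended TDLQ with direct thermal cytotoxicity is deliberately not
  implemented (insufficient prostate data); equivalent doses below ≈39 °C
  elevations rest on extrapolated in vitro ratios.

## Reproducing the bundled studies

```{r, eval = FALSE}
model <- generate_phantom(phantom_config(), seed = 1)
basis <- precompute_bases(model)                  # 36 field + 36 thermal solves
v     <- validation_amplitudes(basis, seed = 1)
gam   <- superposition_gamma(model, basis, v)     # gamma 5%/0.5mm
bt    <- heuristic_dwell_weights(model)           # BT-only plan
lim   <- limits_from_bt_plan(bt$dose, model)
prob  <- plan_problem(model, basis, scale_dose(bt$dose, 0.8), lim,
                      tdlq_preset("AVG"))
opt   <- pso_optimize(prob, pso_control(n_particles = 40, maxit = 250,
                                        stagnation = 60), seed = 2)
opt$metrics$V100
```

`scripts/acceptance.R` chains exactly these steps end to end.
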