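---
title: "Quantifying left-ventricular flow components and kinetic energy from 4D flow CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular flow components and kinetic energy from 4D flow CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

4D flow cardiovascular MR acquires all three velocity components in a 3D
volume over the cardiac cycle, retrospectively gated so the reconstruction
represents one averaged, periodic beat. Given that velocity field plus
end-diastolic (ED) and end-systolic (ES) segmentations of the left ventricle
(LV), the transit of blood through the LV can be quantified by Lagrangian
particle tracing: a pathline is emitted from the center of every ED-mask
voxel and integrated forwards in time to the next end-systole (through
systole) and backwards to the previous end-systole (through diastole), so
each trajectory spans exactly one cardiac cycle. Each pathline represents a
blood volume equal to one voxel.

Testing each pathline's backward endpoint (its *origin* at the previous ES)
and forward endpoint (its *destination* at the next ES) for membership in
the ES mask partitions the end-diastolic blood volume into four functional
components:

| origin in ESV | destination in ESV | component |
|---|---|---|
| no  | no  | **Direct Flow** — enters during diastole, ejected this systole |
| no  | yes | **Retained Inflow** — enters during diastole, stays |
| yes | no  | **Delayed Ejection Flow** — resided before, ejected this systole |
| yes | yes | **Residual Volume** — resides at least two cycles |

The two inflow components are further split by diastolic phase. Diastole is
divided into early (E-wave) and late (A-wave) filling at *mid-diastasis*,
operationalized as the reconstructed frame interval during diastole in which
the fewest inflow pathlines cross the mitral valve plane (ties resolved to
the earliest frame — a deterministic surrogate for the visual rule). An
inflow pathline whose first mitral-plane crossing falls before the
mid-diastasis frame time is E-wave inflow; from mid-diastasis until ED it is
A-wave inflow.

For every component (eight in total) the kinetic energy at frame $t_k$ is

$$\mathrm{KE}(t_k) \;=\; \sum_{\text{pathlines } p} \tfrac12\,\rho\,V_p\,\lvert v_p(t_k)\rvert^2 ,$$

with $\rho$ the density of blood (default 1060 kg/m³, configurable and
recorded in every output) and $V_p$ the represented voxel volume. The values
at the ED frame — KE at ED and its volume-normalized form KE/ml at ED — are
the *pre-systolic* energetic summaries used for group comparison.

## Preprocessing

Phase-contrast data carry two artifacts the pipeline corrects before any
tracing:

* **Background phase offsets.** A full 3-D polynomial of total degree ≤ 4
  (35 monomials) is least-squares fitted, per velocity component, to the
  time-averaged velocity over static-tissue voxels, with coordinates scaled
  to $[-1,1]$ per axis for conditioning; the fitted offset field is then
  subtracted from every frame. One offset per component is fitted rather
  than per-frame fits: the background error of a gated phase-contrast
  acquisition is static over the cycle, and a single spatial polynomial is
  the standard model. Fitting fewer static voxels than monomials, or a mask
  that does not span the basis, raises a rank error that advises enlarging
  the mask or lowering the order.
* **Phase wraps.** A velocity beyond ±VENC aliases by multiples of 2·VENC.
  The temporal algorithm walks each voxel's frames in order and corrects any
  jump exceeding VENC by the nearest multiple of 2·VENC. VENC is the
  tightest threshold that cannot fire on physically valid data: a true
  inter-frame change larger than VENC is indistinguishable from a wrap.
  Voxels requiring more than 3 corrections on one jump are left unmodified
  and flagged unreliable. The procedure is idempotent, and on noiseless
  wrapped data it restores the original field exactly.

Static tissue should be supplied as a mask; a helper flags voxels whose
temporal speed variation falls below a percentile as a fallback, but an
explicit mask always wins, since automatic detection is a heuristic.

## Numerical choices

* **Integrator.** Fixed-step classical RK4 with the step defaulting to ¼ of
  the frame interval (`step_fraction`), aligned to the frame grid: each
  frame interval is divided into `round(1/step_fraction)` equal substeps.
  Alignment matters because the interpolated field is piecewise linear in
  time with kinks at frame times; within a substep the right-hand side is a
  polynomial of degree ≤ 1 in time, which RK4 integrates exactly. On
  spatially uniform fields the tracer therefore reproduces the exact
  displacement integral to floating point, and on the rotation benchmark the
  observed convergence order is 4.
* **Interpolation.** Trilinear in space, linear in time, with the time axis
  periodic (frame $n$ wraps to frame 1) — backward tracing from ED crosses
  the reconstruction boundary, and a gated average cycle has no separate
  "previous beat" data.
* **Out-of-field pathlines** freeze at their last inside position, keep
  their represented volume, and are flagged; their fraction is a QC metric.
  Terminating them instead would silently destroy volume and break the
  partition invariant (components must sum to the EDV exactly).
* **Endpoint membership** uses nearest-voxel lookup in the binary ES mask,
  not mask interpolation: reproducible, no fractional membership.
* **Mitral crossings** are detected as sign changes of the plane's signed
  distance between consecutive trajectory samples; the crossing time is
  linearly interpolated between the bracketing samples. A crossing exactly
  at the mid-diastasis frame time is A-wave (the A interval runs *from*
  mid-diastasis). Inflow pathlines with no detected crossing (possible with
  frozen or noisy traces) are assigned by nearest-approach time and counted
  in the QC report, preserving E + A = parent exactly.
* **Per-frame pathline speed** defaults to the interpolated field speed at
  the pathline position (`speed_source = "field"`); central differencing of
  the positions is available (`"trajectory"`) and agrees exactly on steady
  uniform flow. The field-based default uses the measured data directly and
  is robust to position noise.
* **QC discrepancy denominator.** Inflow = Direct Flow + Retained Inflow,
  outflow = Direct Flow + Delayed Ejection Flow, and the discrepancy is
  $|in - out| / \mathrm{mean}(in, out) \times 100$. The symmetric mean
  avoids a direction bias that a one-sided denominator would introduce; the
  15% exclusion threshold is configurable (`qc_max_discrepancy_pct`).

## The statistics stage

Per-subject result tables (one row per subject: group, QRS duration, and the
per-component volumes and pre-systolic energetics) are compared with a
normality-routed procedure: each group is tested with the one-sample
Kolmogorov–Smirnov test against a normal with estimated parameters
(Lilliefors correction, the appropriate variant when mean and SD come from
the sample itself) at α = 0.05; both groups normal routes to the
pooled-variance unpaired Student's t test (Welch by flag), otherwise to the
Mann–Whitney U test. Zero-variance groups, and groups below the Lilliefors
minimum of n = 5, route conservatively to Mann–Whitney with an explicit
flag. Because group mean, SD and n are sufficient statistics for the pooled
t branch, published summary tables can be re-tested directly
(`summary_t_test`). Associations with QRS duration use ordinary
least-squares simple regression (slope, R², two-sided P). P values print to
three decimals with "< 0.001" below that. Under a simulated null (normal
data, n = 11 per group) the routed procedure holds its nominal 5% type-I
error within simulation noise.

## The synthetic phantom and what it does (not) show

No patient data accompany the method, so validation rests on a synthetic
phantom designed for *exact* ground truth rather than anatomical realism:

* The **slab phantom** emulates the acquisition's data model — by default
  ~40 reconstructed frames per cycle, 2.8 mm isotropic voxels, VENC
  120 cm/s — with a spatially uniform axial velocity $u(t)\hat x$ over a
  support slab that contains every pathline excursion (zero in the far
  field, which doubles as static tissue). The ED and ES masks are axial
  slabs sharing their basal face; the mitral plane sits on that face and the
  aortic plane on the apical face of the ES slab. The waveform is piecewise
  (systolic pulse, E-wave, zero-flow diastasis, A-wave; rectangular or
  half-sine segments, amplitudes in cm/s).
* **Ground truth is closed-form.** Because the field is uniform where
  pathlines travel, a seed at axial position $x$ lands exactly at
  $x + D_{fwd}$ and originates at $x - D_{bwd}$, where $D_{fwd}, D_{bwd}$
  are the exact displacement integrals of the *sampled, linearly
  interpolated* waveform over systole and diastole — the same continuous
  field the integrator sees. Component membership, E/A crossing times
  (quadratic-in-time inversion per frame interval), the mid-diastasis frame
  and every KE curve ($\tfrac12\rho V u(t_k)^2$ per member volume) follow
  analytically, so pipeline output can be compared to truth at **zero
  voxels** of tolerance, and is — over dozens of randomized configurations.
  An independent brute-force per-seed oracle (plain loops, trapezoid
  integrals, nearest-voxel lookup) checks the closed form itself.
* The default waveform amplitudes (6.2 / 24 / 0 / 10.5 cm/s) were chosen
  once so that inflow and outflow volumes balance (QC passes), Direct Flow
  and both its E/A subvolumes are non-empty, and every pre-diastasis frame
  interval sees at least one mitral crossing, which pins the detected
  mid-diastasis to the zero-flow segment.
* **Structural differences from real hearts.** A uniform unidirectional
  field preserves axial ordering, so Direct Flow and Residual Volume cannot
  both be non-empty, and at most one of Direct Flow A / Retained Inflow E is
  non-empty (the earliest-entering blood is always the furthest downstream).
  Real LVs have recirculating, strongly non-uniform flow with all eight
  components populated. The phantom also has no chamber geometry, valve
  motion, turbulence or MR physics. Passing the phantom suite therefore
  demonstrates that the *bookkeeping* — tracing, classification, E/A
  splitting, energetics, QC — is exact, not that the method's clinical
  values are reproduced; the group-level clinical results depend on patient
  data that are not distributable.
* The **rotation phantom** ($v = \omega \times r$, constant over the cycle)
  is linear in position, which trilinear interpolation reproduces exactly,
  isolating the time integrator: endpoints land on the analytic circle to
  better than $10^{-3}$ relative at the default step.
* **Corruption injection** adds, in order, a degree-4 polynomial background
  offset, phase-wrap folding into ±VENC, and Gaussian noise — exactly what
  preprocessing must remove — leaving the clean field untouched for
  comparison. Injected noise uses an explicit seed recorded in the dataset
  sidecar.

## Problem sizes and conventions

The validation suite uses slab grids of roughly 40–110 × 4–6 × 6 voxels
with 40 frames (hundreds to ~900 pathlines per dataset) and twenty
randomized configurations per property sweep; these sizes make every truth
comparison exact while keeping a full suite run in well under a minute per
file. Voxel indices are 1-based in R with physical coordinates at voxel
centers, $(i - \tfrac12)h$ mm; frame indices are 1-based in memory and
0-based in the JSON sidecar on disk. Internally velocities are m/s,
positions mm, times s; reports use ml, mJ and µJ/ml.

## Known limitations

Masks are inputs: bSSFP segmentation, its manual superposition onto the
velocity grid, and valve-plane placement are upstream of this package.
Valve planes are static (no retrospective valve tracking); only the left
ventricle is analyzed; a single averaged beat is assumed (no beat-to-beat
variability); eddy-current/Maxwell corrections and spatial (as opposed to
temporal) phase unwrapping are out of scope.
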