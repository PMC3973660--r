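---
title: "Modelling left-ventricular electromechanics with fibre and sheet microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling left-ventricular electromechanics with fibre and sheet microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvemech)
```

# Scope and model overview

`lvemech` implements a desk-scale pipeline for studying how myocardial
microstructure — the transmural rotation of the myocyte (fibre) direction
and the laminar organisation of myocytes into sheets — shapes the simulated
contraction of an idealized rat left ventricle. The pipeline has five
physical stages plus a synthetic-data stage:

1. **Geometry.** The ventricle is a thick-walled truncated ellipsoid:
   the wall lies between an endocardial and an epicardial ellipsoid surface
   sharing a centre and axes, cut by a basal plane (default at the
   equator). The packaged dimensions (`rat_lv_geometry()`) are those of a
   rat left ventricle in its unloaded (pre-P) and passively pressurized
   (post-P) states, in cm; the pre-P endocardial half-ellipsoid encloses
   about 0.07 cm^3.
2. **Microstructure.** On each element, material axes (radial r,
   circumferential c, longitudinal l) are rotated into a fibre/sheet/
   sheet-normal frame: first about r by the helix angle
   `theta(w) = R sgn(1 - 2w) |1 - 2w|^n` (w = transmural depth, 0 at the
   endocardium), then about the fibre by the sheet angle `beta(w)`
   (linear or sigmoidal/bimodal transmural profile). Crossing
   R in {50, 60, 70, 80} degrees with n in {0.5, 1, 2, 3} gives the 16
   rule-based models `Sn<n>R<R>`; a regional model instead fits one
   (R, n) pair per region of a 16-region partition to axial
   fibre-direction observations.
3. **Electrophysiology.** The monodomain reaction-diffusion equation is
   solved by linear finite elements with the anisotropic conductivity
   `sigma = sigma_f ff' + sigma_s ss' + sigma_n nn'` and Godunov operator
   splitting (explicit node-wise reaction at `dt_ode`, implicit consistent-
   mass diffusion at `dt_pde`). The cellular model is a two-variable
   excitation/recovery surrogate (Mitchell–Schaeffer family) with an
   affine voltage map; it provides a propagating upstroke and a tunable
   action-potential duration, which is all the downstream coupling
   consumes.
4. **Mechanics.** Quasi-static total-Lagrangian finite elasticity on
   10-node tetrahedra with the exponential strain-energy function
   `W = C0/2 (exp(Q) - 1)`,
   `Q = b_ff E_ff^2 + b_ss E_ss^2 + b_nn E_nn^2 + b_fs (E_fs^2 + E_sf^2) +
   b_fn (E_fn^2 + E_nf^2) + b_sn (E_sn^2 + E_ns^2)` in fibre coordinates,
   plus the convex volumetric penalty `kappa (J ln J - J + 1)`. Active
   contraction adds `T_a f0 (x) f0` along the reference fibre. The cavity
   pressure is a follower load on the endocardium; basal nodes are fixed
   longitudinally only.
5. **Coupling and metrics.** Activation times from the electrophysiology
   mesh trigger a squared-sine tension twitch per mechanics element; the
   mechanics is marched through warm-started quasi-static solves under a
   sigmoidal pressure trace. Global metrics are ejection fraction, ray-based
   wall thickening in a midventricular slice, and base-to-apex shortening;
   local metrics are the cylindrical Lagrangian strains E_cc, E_cl, E_cr
   averaged over long-axis thirds.

# Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `R`, `n` | 70, 1 | deg, – | transmural fibre rotation and profile shape |
| `beta_endo/epi` | +45 / −45 | deg | sheet-angle endpoints (both profiles) |
| `k` | 30 | – | bimodal sheet sigmoid steepness (10–90% transition over ~0.15 wall) |
| `C_m`, `chi` | 1, 1400 | µF/cm², 1/cm | membrane capacitance, surface-to-volume ratio |
| `sigma_f`, cross | 2.15, `sigma_f`/4 | mS/cm | conductivities; calibrated (see below) |
| `C0`, `kappa` | 0.88, 100 | kPa | stress scale; volumetric penalty |
| `b` (orthotropic) | 6, 7, 3, 12, 3, 3 | – | exponents in Usyk order |
| `b` (transverse) | 6, 4.3, 4.3, 7.5, 7.5, 4.3 | – | sheet/normal-averaged set |
| `p_end`, `t_mid`, `tau` | 1, 30, 6 | kPa, ms, ms | cavity-pressure sigmoid |
| `T_max`, `t_twitch` | 35, 90 | kPa, ms | twitch peak tension and duration |
| `duration`, `dt_mech` | 60, 1 | ms | simulated interval; mechanics step |
| noise sd | 15 | deg | angular dispersion of synthetic fibre data |

The transversely isotropic exponent set is obtained by averaging the
orthotropic sheet and sheet-normal entries; because `b_ss = b_nn = b_sn`
there, the law is *exactly* invariant to rotations of the sheet plane
about the fibre — the operative meaning of transverse isotropy, and a
unit-tested identity.

The conductivity defaults are the output of the packaged calibration
procedure (`calibrate_conductivities()`): planar-wave simulations on a
cubic wedge with straight fibres, rescaling `sigma_f` by the square of the
velocity mismatch (conduction velocity scales with the square root of
conductivity) until the fibre velocity matches 0.06 cm/ms, with a
fibre:cross-fibre velocity ratio of 2. These targets are rodent-plausible
declared defaults, as is every value in the table; all are configurable.

# Design choices

**Meshing.** No meshing library is available in the target R stack, so the
shell is meshed by a structured parametric grid (depth x azimuth x
longitude) whose hexahedral cells are split into six tetrahedra along a
fixed corner diagonal. The split pattern is translation-invariant in index
space, which makes shared face diagonals agree between neighbours —
including across the periodic azimuthal seam — so the mesh is conformal;
apex cells collapse onto per-layer pole nodes and reduce to three
tetrahedra each. Nodes carry their construction depth (the normalized
position along the local transmural ray), which defines the transmural
depth field and, through its element-wise gradient, the radial material
axis.

**Structure frames.** With the right-handed material triple (r, c, l),
the helix rotation gives `f = cos(theta) c + sin(theta) l` and the sheet
rotation `s = cos(beta) r - sin(beta) l'` (l' the co-rotated longitudinal
axis). The sheet normal is taken as `n = f x s` so that every (f, s, n)
triple is right-handed with determinant +1; at zero angles n is then
*anti*-parallel to l. Since f, s and n enter the conductivity and the
material law only through outer products, the sign is immaterial, and the
right-handed convention keeps one orientation invariant across the whole
field.

**Unloaded geometry.** `estimate_unloaded()` implements the iterative
shrink-and-inflate estimation (bisection on the cavity-volume mismatch of
the inflated candidate). The default coupled pipeline does not re-run it:
the packaged pre-P dimensions already describe the unloaded state, and the
estimation is a one-off preprocessing step, kept and tested as its own
operation.

**Simulation duration.** The default simulated interval is 60 ms: with the
default twitch (90 ms) and apical activation completing within ~20 ms,
cavity volume reaches its minimum — full contraction — at 55–60 ms, and a
longer march only tracks relaxation. Metrics therefore compare the first
and last samples of the default run, i.e. beginning and end of
contraction.

**Rigid modes.** Fixing only the longitudinal displacement at the base
leaves two in-plane translations and the rotation about the long axis as
zero-energy modes. They are removed by penalizing the aggregate rigid
modes of the base ring (net translation/rotation), which exerts no force
on ring dilation or ovalization — per-node springs were rejected because
they measurably bias the inflation (about 1% of cavity volume at spring
stiffnesses large enough to stabilize the solver).

**Solvers and tolerances.** Newton iterations terminate at a relative
residual of 1e-8 (absolute floor 1e-10); diverging load increments are
halved automatically (at most 6 halvings). The tangent is factorized by a
sparse Cholesky of its symmetrized form — the unsymmetric part comes only
from the follower-pressure boundary term and is small — with an
unsymmetric sparse LU as fallback. The diffusion system is factorized once
per run. Ties in the regional-fit grid search are broken towards smaller
n, then smaller R, making the fit fully deterministic; fits ending on the
search boundary are flagged rather than silently returned.

**Degenerate inputs.** Transmural depths outside [0, 1] are clamped (and
reported); near-apex elements where the long axis parallels the radial
axis fall back to an azimuthal circumferential direction; elements whose
centroid lies on the long axis are excluded from cylindrical strains;
unactivated nodes produce a warning and zero twitch tension.

# What the synthetic data emulate — and what they do not

`synth_fibre_observations()` emulates the primary eigenvector of a
diffusion tensor: the true fibre axis of each element, rotated by a
wrapped-normal angle (default sd 15 degrees, the dispersion scale reported
for rat diffusion-tensor fibre fields) about a random perpendicular axis,
with a random sign flip because eigenvectors are axial. Wrapped-normal
noise was chosen over a von Mises–Fisher distribution for direct control
of the angular standard deviation. The generator does *not* simulate the
diffusion-MR signal, partial-volume averaging, spatially correlated noise,
or regionally varying dispersion; parameter-recovery results on these data
therefore show that the fitting machinery is correct and well-conditioned
at realistic noise levels, not that real DT-MRI data would be fitted with
the same accuracy.

`analytic_motion()` composes in-plane scaling, long-axis scaling and twist
about the long axis, all with closed-form deformation gradients. Every
global and local metric has a closed form under this motion, which makes
the metrics module fully testable without a physics run; the motion is an
oracle, not a model of cardiac kinematics.

# Problem sizes

The packaged defaults are deliberately desk-scale: mechanics meshes of a
few hundred quadratic tetrahedra (divisions `c(2, 12, 6)`),
electrophysiology meshes of a few thousand linear tetrahedra, 9^3-cell
calibration wedges, and 60 ms simulated intervals. The study-shape
conclusions exercised in the test suite (conduction-velocity calibration,
near-incompressibility, parameter recovery, microstructure effects on
strain) are all formulated to be meaningful at this scale; convergence
checks (mesh refinement, time-step halving) bound the discretization
sensitivity rather than eliminate it.

# Known limitations

* The geometry is idealized (no right ventricle, no papillary muscles) and
  the basal plane is flat by construction.
* The cellular electrophysiology and contraction models are
  phenomenological surrogates: a two-variable excitation/recovery system
  and a squared-sine twitch. They reproduce propagation, a short rodent-
  like action potential and a tension transient of controllable magnitude
  and duration, but no ionic or crossbridge detail; restitution, rate
  dependence and length/velocity dependence of tension are out of scope.
* Coupling is one-way (voltage to tension); there is no mechano-electric
  feedback and no deformation feedback on conductivity.
* The pressure boundary condition prescribes the trace directly; no
  circulation model or isovolumic-phase constraint is enforced.
* The sheet-angle endpoints of the transmural profiles are declared
  defaults (+45/−45 degrees). Sensitivity runs during development showed
  that the *sign* of the small ejection-fraction difference between the
  orthotropic and transversely isotropic laws depends on exactly such
  unreported structural settings; see the package README for how the
  acceptance suite treats this comparison.
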