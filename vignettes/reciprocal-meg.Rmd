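---
title: "Reciprocal MEG forward modeling: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal MEG forward modeling: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MEG source estimation needs the gain (leadfield) matrix `L`, the `M x N`
linear map from the strengths of `N` cortical current dipoles to the outputs
of `M` sensors.  With realistic multi-layer conductor models every entry
requires a forward solve, and the classical column-wise assembly — one
quasi-static forward solution per dipole — makes dense source spaces
(hundreds of thousands of dipoles) expensive, because `N >> M` in every
practical system.

Lorentz reciprocity turns the computation around.  Driving sensor `i` as an
induction coil with current `I(t) = I0 cos(wt)` produces an electric field
`E_i` inside the head, and for a dipole with moment `p n_j` at `r_j`,

    L[i, j] = n_j . E_i(r_j),

so one induction-coil (TMS-style) forward solve per *sensor* fills an entire
*row* of `L`.  The number of solves drops from `N` to `M` — a few hundred at
most.  `recmeg` implements this row-wise assembly, the classical column-wise
assembly it must agree with, the minimum-norm inverse chain, and a
simulation framework for evaluating source localization, on synthetic
phantoms with analytic oracles.

## The charge-based boundary element solver

The induced field is computed from the surface charge density at
conductivity interfaces.  For isotropic piecewise-constant conductivity the
charge density `rho` on the interfaces satisfies a second-kind integral
equation driven by the conductivity contrast

    K = (sigma_in - sigma_out) / (sigma_in + sigma_out),

collocated at face centers of the triangulated interfaces.  The package
stores the scaled unknown `g = rho / (2 eps0)`, which has E-field units; in
these units the discrete equation at face `n` reads

    g_n - K_n n_n . sum_{m != n} A_m g_m (r_n - r_m) / (2 pi |r_n - r_m|^3)
        = K_n n_n . E_inc(r_n)

with no permittivity constant anywhere.  The side limits of the normal
field follow directly from the jump conditions,

    n.E_out = sigma_in / (sigma_in - sigma_out) * 2 g,
    n.E_in  = sigma_out / (sigma_in - sigma_out) * 2 g,

which is the shortcut used for reciprocal rows: after one charge solve the
whole row is read off the cortical surface with no secondary-field
evaluation.  The factor 2 is fixed by validating against a side-limit
oracle (total field evaluated a fraction of a face size off the surface)
and, end to end, by row-wise vs column-wise agreement.

Numerical choices:

* **Collocation and near-field quadrature.**  Faces are the discretization
  unit; interactions use the one-point centroid rule beyond a neighbor
  radius of `2 * sqrt(mean face area)` and a barycentric subdivision rule
  inside it (6-way edge split, 36 sub-triangles; 18- and 45-way splits as
  the evaluation point approaches the face scale).  The same face-averaged
  rule is applied to the dipole kernels of the column-wise path: a dipole a
  fraction of a face size away from an interface makes the one-point
  collocation sample of its near-singular field meaningless, and averaging
  over sub-centroids restores usable accuracy without adaptive mesh
  refinement.  The split
  factors are chosen so no sub-centroid coincides with the parent centroid,
  which lets the single-layer potential be evaluated at a face's own center
  (needed for the volume-current magnetic field below).  Sub-points
  coinciding with the target contribute zero (principal value); the `m = n`
  self-term is excluded — it is absorbed in the identity part of the
  operator.
* **GMRES.**  Restart-free, matrix-free (the matvec is a compiled pairwise
  summation), initial iterate equal to the right-hand side (the first-order
  Born-type approximation), relative residual tolerance `1e-4`, iteration
  cap 60.  The residual history is recorded and is non-increasing by
  construction.
* **Charge neutrality.**  Each closed interface carries zero net charge in
  the continuum.  The collocation solution leaves a small spurious monopole
  (it plateaus near 2 % of the absolute charge under refinement and is
  independent of solver tolerance); a uniform charge shell has no interior
  field, so interior quantities are unaffected, but the solver projects the
  area-weighted mean charge out of every interface after the solve
  (`enforce_neutrality = TRUE`) so exterior potentials are clean and the
  neutrality invariant holds by construction.
* **Backends.**  The matvec contract is pluggable; this package ships the
  direct `O(F^2)` summation.  A fast-summation backend would have to agree
  with it to the configured `matvec_precision`.

## Sensors as induction coils and as flux integrators

Magnetometers are square loops (default side 25.8 mm — a representative
whole-head-array size; all coil dimensions are configurable because vendor
drawings are not public).  Planar gradiometers are two coplanar rectangular
loops (default 12 x 26 mm) wound in opposition with centers a baseline
(default 16.8 mm) apart.

* In the **reciprocal (driven) role** each loop is discretized into current
  elements of equal arc length (default 16 per loop; element directions sum
  to zero for closed loops).  The primary field of an element is the
  quasi-static `1/r` kernel `E = -(mu0/4pi) (dI/dt) s_j / |r - p_j|`, with
  `dI/dt = 1 A/s` and the angular frequency fixed to `1 /s` (it is
  arbitrary in the quasi-static regime).  With the cosine current
  convention the in-phase reciprocal field is minus the field chain
  evaluated at `dI/dt = +1`; the sign is fixed once in the row assembly and
  verified against the direct path.  Gradiometer loops are driven with
  opposite signs.
* In the **measuring role** sensor outputs are flux integrals approximated
  by tensor-product Gauss-Legendre quadrature: 64 points per magnetometer,
  64 per gradiometer coil (128 total), weights summing to the loop area.
  Outputs are reported as flux / area (T) for magnetometers and flux
  difference / (area * baseline) (T/m) for gradiometers, so mixed arrays
  keep per-kind units that the whitening stage can reconcile.

Helmet arrays place sensor triplets (one magnetometer, two orthogonal
planar gradiometers) on a Fibonacci lattice over a spherical cap — 102
sites give the familiar 306-channel layout.

## Column-wise assembly and the analytic oracle

The direct path computes, for each dipole, the charge solution driven by
the dipole's infinite-medium field, the total interface potentials, and the
magnetic field

    B(r) = B_primary(r)
         - (mu0/4pi) sum_S (sigma_in - sigma_out)
                     sum_m A_m phi_m n_m x (r - r_m) / |r - r_m|^3,

the volume-current (surface-integral) form; sensor outputs follow by flux
quadrature.  The sign of the volume term is fixed by derivation from
`J_v = -sigma grad(phi)` and confirmed against the closed-form field of a
dipole in a spherically symmetric conductor, which the package implements
as `sarvas_field()` (radial dipoles are silent; conductivity profile drops
out).  When many columns are needed on one model the dipole solves share a
single dense LU factorization of the operator (below ~9000 faces), which is
algebraically the same system the GMRES path solves; the solve count still
equals the number of dipoles.

Accuracy note: the tangential components of raw `B` inherit the `O(h)`
collocation error of the surface potential (several percent at desk-scale
meshes).  Sensor-level outputs are much more accurate because pickup
normals are close to radial and volume currents contribute no radial field
outside a spherically symmetric conductor; the sensor-level direct-vs-
analytic agreement is at the 0.01–1 % level on the phantoms used here.

## The inverse chain

The inverse follows the standard minimum-norm methodology with fixed
(normal) source orientations:

* **Depth weighting.**  Column norms `w_j = ||L[, j]||` define the source
  covariance `R = diag(w^(-2 * exponent))`, with the prior's dynamic range
  capped at `limit^2` (default limit 10) in the standard way — without the
  cap, sources the array barely sees receive an unbounded variance boost
  and capture reconstruction energy.  The default `exponent = 1` makes the
  whitened effective columns unit norm (the depth-weighting parameter
  `p = 1` convention); `exponent = 0.25` reproduces the alternative
  `diag(w^(-1/2))` reading found in the literature.  Both are pinned by
  tests; the choice is a documented knob because the two printed
  conventions genuinely conflict.  The phantom studies below use
  `exponent = 0.25`: on a sparse 48-magnetometer array the full
  column-normalization prior over-boosts deep sources and displaces even
  well-seen superficial probes, while the gentler reading localizes them
  to a few millimeters.
* **Noise covariance and whitening.**  The covariance is the pooled
  empirical covariance of baseline samples plus diagonal loading
  (`loading * mean(diag)`).  The whitener is the eigendecomposition-based
  inverse square root with eigenvalues below `1e-10 * max` truncated —
  mixed magnetometer/gradiometer units make the covariance ill-conditioned.
* **Regularized operator.**  `Mbar = R Lbar' (Lbar R Lbar' + lambda2 I)^-1`
  with `Lbar` the whitened gain.  With `R = I`, `lambda2 = 0` this is the
  Moore-Penrose pseudoinverse (verified to 1e-8), and in general it matches
  an SVD closed form to 1e-10.  `lambda2 = 1 / snr^2` with the whitened
  gain trace-normalized (`trace(Lbar R Lbar')/M = 1`); the scaling leaves
  the unregularized solution unchanged.
* **dSPM.**  Per-source noise variances are the diagonal of
  `M Sigma M'`; the normalized estimate `x* = x / sqrt(diag)` behaves like
  a z-score.  (The printed form of the normalization in the source
  literature is garbled; the standard per-source normalization is
  implemented.)  dSPM is kept out of the simulated-data protocols, where a
  noise covariance estimated from simulation would bias the comparison.

## Simulation framework and phantoms

* **Sphere phantoms** are nested icospheres (or `k`-way tessellations for
  intermediate densities) with scalp/skull/brain conductivities
  0.25 / 0.01 / 0.275 S/m; CSF (1.654), GM (0.275) and WM (0.126 S/m) are
  used where those tissues appear.  The **cortex phantom** is a radially
  modulated sphere `r = R (1 + a sin(k theta + psi1) sin(k phi + psi2))`
  (default `R = 60 mm`, `a = 6 mm`, `k = 6`, seeded phases), built as a
  WM/GM pair 3 mm apart with one dipole per WM face shifted 0.5 mm outward
  along the normal.  Real cortices are not sinusoidal: the phantom has
  controllable sulci and a known ground truth, but no hemispheric fissure,
  no variable thickness, and no skull holes, so passing phantom tests shows
  internal consistency and plausible scale, not clinical accuracy.
* **Noise model.**  `K` dipoles drawn area-weighted over the mid-surface
  between WM and GM, oriented normally; their direct forward fields form an
  `M x K` noise leadfield, and noise draws are `eps = L X / ||L X||` with
  standard-normal `X` (reference protocol `K = 2000`; the phantom studies
  use `K = 400`).
* **SNR mixing.**  `s(eta) = (1 - eta) eps + eta b` with unit-norm signal
  and noise; `eta` is found by bisection so that
  `std(s) / std((1 - eta) eps)` hits the target to 0.1 %.  Targets below 1
  are unreachable (the ratio at `eta = 0` is 1).  Tested levels:
  81, 27, 9, 3, 2, 1.5.
* **Error maps** probe each dipole with
  `s = (1 - lambda0) u_j + lambda0 eps`, the noise draw having the probed
  dipole's strength forced to zero.  Both components are unit-normalized —
  with hundreds of unnormalized noise columns the noise term would swamp
  any signal at every nominal noise percentage, so the normalized reading
  is the only workable one; this is stated here because the convention
  matters when comparing absolute noise levels.
* **Localization metrics.**  Peak (largest |strength|), thresholded region
  (`|x| >= T max|x|`, default 75 %), centroid (unweighted mean of region
  positions; area-weighted optional), Euclidean distances to ground truth.
  ROC/AUC treats membership in a curvature-tagged target region (faces with
  mean curvature below a threshold, grown around a seed until a requested
  area fraction — default 40 % — is covered) as the positive class, sweeping
  the activation threshold; AUC is exact against brute-force enumeration.

## Reference phantom configuration

The acceptance checks and `scripts/acceptance.R` run, per run:

| study | configuration |
|---|---|
| reciprocity equivalence | 3 shells 90/85/80 mm, `k = 11` (2420 faces/shell; coarse pair at `k = 5`), 6 magnetometers, 500 random interior sources |
| analytic oracle | homogeneous sphere, icosphere subdivision 4 (5120 faces), 40 tangential + 40 radial dipoles at 0.7 R |
| solver correctness | two shells at `k = 3` (360 faces) vs dense LU |
| cortex phantom study | 4 surfaces (skin/skull/GM/WM; the CSF compartment is merged into the skull interior at this scale) at `k = 7` (980 faces each), 48 magnetometers, 980 sources, noise model `K = 400`, depth exponent 0.25, 100 Monte-Carlo samples per noise level; the probed dipole is the best-seen cortical source under the helmet, mirroring the hand-picked well-visible source of the reference protocol |

These sizes are the package's reference configuration; they keep a full run
in minutes on one core while staying in the mesh-resolution regime where
the discretization errors measured above are small.  All Monte-Carlo stages
take explicit seeds.

## Known limitations

* Isotropic conductivity only; no anisotropic skull or white matter.
* No fast-multipole backend: dense `O(F^2)` interactions bound practical
  models to tens of thousands of faces.
* No adaptive mesh refinement near sources; very shallow dipoles (closer to
  a surface than about one face size) lose forward accuracy, which is why
  the phantoms keep sources at least half a face size away from interfaces.
* Sensor geometry is idealized (rectangular loops, no pickup-coil
  electronics); axial gradiometers are not modeled.
* The CLI exchanges meshes as ASCII STL/OFF/PLY and sensor vectors as TSV;
  native acquisition formats are out of scope by design, with the reader
  interface kept narrow so an adapter can be added.
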