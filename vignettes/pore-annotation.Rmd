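---
title: "Annotating ion channel pores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating ion channel pores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescope)
```

## The problem

Whether an ion channel structure is conductive is conventionally judged from
the physical dimensions of its pore: if the narrowest constriction exceeds
the radius of the hydrated ion, the structure is called open. This criterion
misses *hydrophobic gates*: pore segments that are wide enough to pass a
hydrated ion but are lined by hydrophobic side chains, so that water
spontaneously evaporates from them. The resulting desolvation penalty blocks
ion flow without any steric occlusion. Detecting such gates requires three
things beyond a radius profile: knowing which residues face the pore and how
hydrophobic they are, and — when a solvated structure or simulation
trajectory is available — measuring the equilibrium water density along the
pore and converting it into a free-energy profile of pore hydration.
`porescope` implements this pipeline.

## The model, stage by stage

### Hard-sphere probe sweep

The protein is modelled as a set of van der Waals spheres: atom $j$ at
$\mathbf{Q}_j$ with radius $r_j$ (waters excluded). The probe radius at a
point $\mathbf{P}$ is

$$R(\mathbf{P}) = \min_j \left( \lVert \mathbf{Q}_j - \mathbf{P} \rVert - r_j \right),$$

the largest sphere centred at $\mathbf{P}$ that touches no atom. Starting
from an initial point $\mathbf{P}_0$ (by default the centre of geometry of
the protein), the probe is stepped by $\Delta v$ along the channel direction
$\mathbf{e}_v$; in each plane normal to $\mathbf{e}_v$ the probe position is
optimized to maximize $R$ using a two-dimensional Nelder–Mead (downhill
simplex) search. A sweep terminates when the optimized radius exceeds a
stop threshold (default 1 nm), i.e. the probe has left the pore; the sweep
is then repeated in the opposite direction. Nelder–Mead is used rather than
a global optimizer because a global search can jump out of the pore into
neighbouring cavities.

Optimizer details not fixed by the method's description and decided here:
the initial simplex is the seed point plus two vertices offset by
$0.1\,\Delta v$ along the in-plane basis vectors; coefficients are the
standard reflection/expansion/contraction/shrink values (1, 2, 0.5, 0.5);
the in-plane basis is built deterministically by Gram–Schmidt against the
canonical axis least aligned with $\mathbf{e}_v$. The loop exits early when
the simplex has degenerated to machine precision, since further iterations
cannot move it; this is why a 100-iteration profile and a 2000-iteration
reference profile agree to far better than the 0.001 nm convergence
tolerance the method is expected to meet.

### Centerline and radius profile

The optimized probe centres are interpolated by a cubic spline that passes
exactly through every point. The construction used here (the reference
description leaves it open): natural cubic interpolating splines per
coordinate against the chord-length parameter, then reparameterization to
arc length by per-panel Gauss–Legendre quadrature with a monotone
(Hyman-filtered) inverse mapping. The resulting curve $\mathbf{S}(s)$ is
unit-speed to ~1e-3 and reproduces the probe points at their arc lengths to
1e-6 nm. Natural (rather than not-a-knot) end conditions were chosen and
are configurable in principle by refitting; the choice only affects the
outermost knot intervals, which lie in the pore mouths.

The continuous radius profile $R(s)$ interpolates the probe radii against
arc length on a uniform grid whose default spacing equals the probe step —
the native resolution of the sweep.

### Curvilinear coordinates

A particle at $\mathbf{Q}$ is assigned coordinates $(s, \rho, \phi)$: $s$ is
the arc length of the closest curve point (minus the arc length of
$\mathbf{P}_0$'s projection, so $s = 0$ at the initial point in every frame,
keeping trajectory frames aligned), $\rho$ the distance to the curve, and
$\phi$ the angle around it. The closest-point problem is solved globally:
a coarse scan on a dense precomputed sampling (spacing $\Delta v / 4$)
followed by vectorized bracket refinement and a parabolic polish. For a
straight centerline this reduces exactly to cylindrical coordinates.

Two conventions worth noting. First, particles whose nearest curve point is
an endpoint (bulk water beyond the pore mouths) receive $s$ by signed linear
extension along the endpoint tangent, so every water obtains a finite
coordinate for the density estimate. Second, $\phi$ is measured against a
rotation-minimizing frame (double-reflection transport) rather than the
Frenet frame, which flips at inflection points; $\phi$ is only meaningful
relatively and is integrated out of all 1-D profiles.

### Water density and free energy

The 1-D water probability density is a Gaussian kernel density estimate
over the $s$-coordinates of all $N$ water oxygens,
$P(s) = N^{-1} \sum_i K_h(s - s_i)$. Assuming an approximately circular
cross-section of local radius $R(s)$, the number density is
$n(s) = N P(s) / (\pi R(s)^2)$ and Boltzmann inversion gives

$$G(s) = -k_B T \ln \frac{P(s)}{\pi R(s)^2} + C,$$

with $C$ fixed by the convention that $G$ averages to zero over a designated
bulk band. The default band is the outermost 10% of the *hydrated*
$s$-range at each end: the traced pathway usually extends past the solvated
region into the pore mouths, and a band defined on the whole grid could
contain no water at all. An explicit band inside well-sampled bulk is
preferable when one is known, since kernel mass leaks outward at range
edges. The number-density report carries both raw nm⁻³ values and values
relative to the band's bulk density.

The bandwidth $h$ is the decisive parameter. Very small $h$ produces noisy
densities that hit zero in dry regions, making $G$ singular; very large $h$
flattens the profile until barriers disappear. The default $h = 0.14$ nm —
about the radius of a water molecule — keeps densities physically
interpretable and comparable between structures, whereas the AMISE-optimal
bandwidth varies with pore volume. AMISE selection is available as
Silverman's normal-reference rule $h = 1.06\,\hat\sigma N^{-1/5}$ (with a
Sheather–Jones plug-in alternative); the criterion fixes only the target
(asymptotic MISE), not the estimator, so the estimator is documented and
fixed here.

Grid points whose density falls below the floor $1/(N \cdot \text{range})$
are flagged *dehydrated*; their $G$ is reported as a lower bound computed at
the floor rather than silently clipped or left infinite. De-wetted segments
are reported as maximal runs of grid points below a fraction of the bulk
number density (default 0.2) spanning at least a minimum length (default
0.3 nm, roughly one water diameter).

### Residue classification and hydrophobicity

A residue is *pore-lining* when its centre of geometry (all non-hydrogen
atoms — side chain and backbone; a side-chain-only variant would be a
one-line change and was not needed) satisfies
$\rho^{\mathrm{cog}} \le R(s^{\mathrm{cog}}) + R_{\mathrm{thres}}$, with
$R_{\mathrm{thres}} = 0.75$ nm a typical value for an α-helical pore. A
pore-lining residue is *pore-facing* when its α-carbon is at least as far
from the centerline as its centre of geometry — the side chain points
inward. The source description prints corrupted inequality symbols for both
tests; the prose fixes the direction, and both comparisons are implemented
inclusively at the boundary. For trajectories the two indicators are
averaged over frames and written to the occupancy (lining) and B-factor
(facing) columns of an annotated PDB.

Hydrophobicity scales are normalized two-sidedly to $[-1, +1]$: the scale is
oriented so larger means more hydrophobic, positive values are divided by
the maximum, negative values by the magnitude of the minimum. This preserves
the scale's natural zero while mapping the most hydrophobic residue to +1
and the most hydrophilic to −1. Four scales are bundled (Wimley–White
interface — the default — and octanol, Kyte–Doolittle, Hessa); custom
two-column files are accepted.

The continuous profile is a Nadaraya–Watson kernel-weighted average of the
pore-facing residues' normalized values with an unnormalized Gaussian kernel
of span $\lambda = 0.225$ nm (an α-helix rises ~0.15 nm per residue and
roughly every third residue faces the pore). Raw Nadaraya–Watson converges
to the *nearest* residue's value far from all residues; to obtain the
physically sensible decay to zero in bulk, the denominator carries a
constant pseudo-weight $w_0 = e^{-9/2}$ (the kernel evaluated at $3\lambda$).
Inside the pore, where kernel mass is appreciable, $w_0$ perturbs the
profile by under 2%; far outside it pulls the profile to zero.

A macroscopic reference point for interpreting profiles: the liquid–vapor
grand-potential difference of a cylindrical pore,
$\Delta\Omega = 2\pi R \gamma_{lv}(R + L\cos\theta_e)$, is provided as
`dewetting_free_energy()`.

### Trajectories

Each frame is analysed independently — the sweep is re-run because the
protein moves — and profiles are resampled onto the grid of the first frame
(values beyond a frame's own pathway range take the boundary value). No
structural alignment is performed: the curvilinear system is internal to
each frame, and the $s = 0$ convention keeps frames comparable. Summary
bands are pointwise mean, population (1/n) standard deviation, minimum and
maximum; the frames × grid number-density matrix is exported for
heatmap-style inspection of de-wetting over time.

## The synthetic-pore generator

`make_pore()` builds pseudo-atom pores with analytic ground truth: dense
rings of hard spheres (spacing 0.05 nm, vdW radius 0.12 nm) tracing a
cylinder, Gaussian-waisted hourglass, linear funnel, or a tube around a
circular arc, with flared mouths so sweeps terminate cleanly. Wall
"residues" with known classification are attached: pore-facing residues
carry their side-chain atoms on the wall with the α-carbon behind it,
pore-lining-only residues the reverse, and decoys sit 1 nm outside the
cutoff; waist residues are named LEU and flanks SER (mimicking the
hydrophobic leucine-ring motif of pentameric channels) so hydrophobicity
profiles have signed ground truth.

Two subtleties found and handled during development. For sloped walls the
true probe radius is the minimal distance to the wall *surface*, which is
smaller than the same-plane gap `a(z) − r_wall`; the analytic oracle uses
the min-over-surface form (the two coincide for cylinders and at the
hourglass waist). And every generated fixture is self-checked: the probe
radius at interior ring centres must equal the exact ring-geometry minimum
to 1e-9, and an in-plane optimization must not beat the analytic radius by
more than 0.05 nm (which would mean the probe can leak between wall atoms —
this is an error, not a warning).

`place_waters()` places water oxygens by rejection sampling with linear
density $\propto \pi R(z)^2 e^{-G(z)/k_B T}$ and uniform cross-sections, so
Boltzmann inversion of a perfect estimate would recover the prescribed
$G$ exactly. Placement is deterministic given a seed. The prescribed profile
is a function of the axial coordinate $z$; parameter-recovery tests use
straight fixtures, where $z$ equals the pathway coordinate.

What a green test on these fixtures does *not* establish: fixtures have
rigid, radially symmetric, single-branch pores with ideal water statistics.
Real channels have side tunnels, conformational flexibility, non-circular
cross-sections (which bias the $\pi R^2$ cross-section assumption in
$n(s)$ and $G(s)$), and correlated water dynamics. The pipeline's behaviour
on those features is validated only qualitatively by construction choices,
not by these tests.

## Numerical choices and degenerate inputs

- Lengths are nm internally; PDB I/O converts Å at the boundary.
  $k_B = 0.008314462618$ kJ/(mol·K).
- The probe objective needs no tie-breaking when several atoms attain the
  minimum: only the value enters the optimization.
- Duplicate consecutive probe points are merged (with a warning) before
  spline fitting; fewer than 4 distinct points is an error.
- An initial point whose optimized probe radius already exceeds the stop
  threshold is rejected with advice to supply an interior point.
- KDE with a default range covers all samples ±5 bandwidths, so the density
  integrates to 1 up to Gaussian tail mass (< 1e-6).
- The default vdW radius table is a Bondi-type set bundled as a plain-text
  file; the method's reference description does not name its table, so the
  table is explicitly swappable (`vdw_radius_table(file)`), with lookup
  precedence (residue, atom name) → element → default.
- Profiles evaluated outside their grid take the boundary value; the
  mapping of particles beyond the pore mouths uses tangent extension.

## Known limitations

- Single-branch pathways only: one probe trace per frame, no CAVER-style
  side-tunnel detection.
- The simulated-annealing probe optimizer of the original HOLE lineage is
  deliberately not provided (the simplex variant is the robust one).
- Trajectory input is multi-model PDB; binary MD trajectory formats would
  need external conversion.
- Ion densities, 2-D $(s, \rho)$ densities, and Jacobian-corrected 3-D
  densities are out of scope; only the 1-D marginal with the circular
  cross-section assumption is produced.
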