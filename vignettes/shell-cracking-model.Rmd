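---
title: "A lattice-spring shell model of stratum corneum cracking on papillated skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice-spring shell model of stratum corneum cracking on papillated skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical picture

African elephant skin carries a fine network of micrometre-width channels
that are cracks in the animal's stratum corneum, confined to the troughs
between millimetric dermal papillae.  The hypothesis this package makes
computable is mechanical: the stratum corneum forms as a *shell* — a thin,
brittle sheet whose stress-free rest shape is the curved papillated surface
it grew on — and as new keratinous layers are added underneath, the outer
sheet is pushed outwards.  Because an offset of a curved surface is not
isometric to the surface itself, the displaced sheet cannot keep its rest
metric and rest curvature at once: bending strain concentrates where the
substrate curvature is strongest, in the troughs between papillae, until
the material's failure strain is exceeded and cracks propagate along the
troughs.  The competing explanation — desiccation shrinkage, as in drying
mud — produces a different signature: cracking driven by in-plane tension,
with crack lines that cross troughs and papillae rather than following
them.  The package simulates both protocols on identical substrates and
quantifies the difference.

## Model

The sheet is a triangulated lattice with nodes of mass $m$ and five energy
terms.

* **Stretching.** Each unbroken edge is a spring with energy
  $\tfrac{k_s}{2}\, l_0\, \varepsilon^2$, where
  $\varepsilon = (|e| - l_0)/l_0$ and $l_0$ is the rest length frozen at
  initialisation.  The $l_0$ prefactor makes $k_s$ a per-length material
  stiffness, so refining the mesh does not change the material.
* **Bending.** Each hinge (pair of faces over an interior edge) carries
  $k_b (\theta - \theta_0)^2$ with $\theta$ the signed dihedral angle and
  $\theta_0$ its rest value — nonzero on a curved substrate, which is what
  makes the sheet a shell rather than a plate.  A hinge transmits bending
  only while both incident faces are intact; the dihedral gradient is
  suppressed on degenerate sliver faces (triangle height below
  $10^{-3}$ of the edge length), where it is ill-conditioned.
* **Area.** Each face with three unbroken edges pays
  $\tfrac{k_v}{2} A_0 (A/A_0 - 1)^2$, a weak in-plane volumetric penalty.
* **Substrate.** Each node is tethered to its *foot point* — its initial
  position — offset along the frozen substrate normal by the growth
  height $h$: $\tfrac{k_{sub}}{2}\,|x_i - (p_i + h\,n_i)|^2$.  The
  symmetric tether both transmits the outward push of the growing tissue
  and resists penetration, and the frozen foot points model the tangential
  anchoring of the stratum corneum to the living epidermis underneath.
* **Self-contact.** Node–face pairs not sharing or neighbouring a vertex
  pay $\tfrac{k_c}{2}(d_c - d)^2$ once closer than the contact range
  $d_c$, with forces distributed to the face corners by barycentric
  weights of the closest point.

Quasi-static loading alternates an increment of the control parameter with
relaxation to the steady state of the damped Newtonian dynamics
$m\ddot x = F - \gamma \dot x$ (semi-implicit Euler).  By default the
relaxation accelerates this dynamics with FIRE-style adaptive damping and
time step — the stationary state, $F = 0,\ v = 0$, is identical, and the
plain constant-damping integrator remains available
(`relax(..., method = "damped")`).  The time step is capped at
$0.5\sqrt{m/k_{\max}}$ over the stiffest single-node coupling and halved
automatically on divergence.

### Fracture

An edge breaks when its *effective strain* exceeds the critical strain
$\varepsilon_c$:
$$\varepsilon_{\mathrm{eff}} = \varepsilon_{\mathrm{membrane}}
  + \frac{t_s}{2}\,\bigl|\kappa_e - \kappa_e^0\bigr|,\qquad
  \kappa_e = \frac{2\theta}{h_1 + h_2},$$
the outer-fibre strain of a sheet of thickness $t_s$, with $h_1, h_2$ the
incident triangle heights over the edge.  Boundary edges, and edges whose
hinge has a cracked incident face, carry the membrane term only; a
membrane-only criterion is available as a configuration switch.  Bonds
break strictly one at a time — always the single highest-strain edge, ties
resolved to the lowest edge id — with a full relaxation between breaks, so
cracks propagate from tips instead of shattering at once.  Breaking an
edge removes its spring, its hinge, and the area terms of its incident
faces; no energy term can increase when an edge breaks.

### Protocols

*Growth* raises $h$ in steps of $h_{\max}/16$ up to
$h_{\max} = \langle d \rangle / 6$ (the operating point also used for
reporting: runs are snapshotted when ~3% of edges have broken).
*Shrinkage* scales all rest lengths by $(1-s)$ (rest areas by $(1-s)^2$)
with the tether held at $h = 0$.  Rest hinge angles and rest edge
curvatures stay frozen at their initial values: desiccation is modelled as
an in-plane contraction of the dead material, not a change of its
preferred curvature.  One deliberate consequence is that shrinkage stress
is predominantly membrane tension while growth stress is predominantly
bending.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $k_s$ | stretch stiffness (energy/length) | 1 | sets the unit of stress |
| $t_s$ | sheet thickness (mm) | $\langle d\rangle/10 = 0.2$ | thin-shell regime; sets the bending share of $\varepsilon_{\mathrm{eff}}$ |
| $k_b$ | hinge bending stiffness (energy) | $k_s t_s^2 / (18\,\bar l)$ | thin-plate consistency with the spring lattice ($B = Y t^2/12$ with the triangular-lattice moduli) |
| $k_v$ | area stiffness (energy/area) | $k_s/\bar l$ | comparable in-plane resistance to the springs |
| $k_{sub}$ | tether stiffness (energy/length²) | 1.5 | calibrated so the imposed growth actually reaches the reported operating point: ~3% of edges broken within $h \le \langle d\rangle/6$; a much softer tether under-loads the sheet and cracking stalls before the offset is reached, a much stiffer one pins the nodes and suppresses the strain redistribution that localises cracks |
| $k_c,\ d_c$ | contact stiffness and range | 1, $\bar l/2$ | short-range penalty, active only near closed cracks |
| $\varepsilon_c$ | critical strain | 0.3 | standard operating point |
| $\gamma$ | damping | $2\sqrt{m\,k_{sub}}$ | near critical for the tether mode (plain integrator) |
| $\tau$ | trough threshold | 0.4 | places the trough boundary on the steep bump flank |

All lengths are millimetres.  $\bar l$ is the mean mesh edge length;
meshes sample the substrate at $\langle d\rangle/20$ by default.

## The synthetic substrate

`generate_papilla_substrate()` emulates the quasi-regular lattice of
millimetric dermal elevations: hexagonally arranged papilla centres with
seeded 2D Gaussian jitter (default $\langle d\rangle = 2$ mm spacing,
jitter SD 0.2 mm), each carrying a compactly supported smooth bump
$b(r) = A \exp\!\left(1 - \tfrac{1}{1 - (r/R)^2}\right)$ for $r < R$
(default $A = 0.6$ mm, $R = 0.8$ mm), combined with a $p$-norm smooth
maximum ($p = 8$) so troughs are genuinely flat and overlapping bumps form
no spurious ridges.  The default domain of 7 mm × 6 mm holds about 15–16
papillae and, at the default sampling, about 5,000 mesh vertices — the
problem size used by the package's own end-to-end checks; the amplitude
and radius were fixed once to reproduce the qualitative morphology of
papillated skin (rounded bumps separated by connected troughs) and are
exposed in the configuration.

What the generator does *not* emulate: the apex-height variability,
papilla clumping and anisotropy of real dermal lattices, curvature of the
body surface, and any spatial gradient of material properties.  Passing
the package's checks on this substrate therefore demonstrates the
mechanism — bending-driven, trough-confined cracking under growth and its
absence under shrinkage — not a quantitative match to any individual
animal.

## Statistics of crack networks

Broken edges project to a 2D network: one node per broken edge (rest
midpoint, height dropped), one segment between broken edges adjacent on
the mesh.  Since bonds break along the local tension while the *seam*
(crack line) runs perpendicular to them, adjacent broken bonds touch at
shared vertices; vertex adjacency (a superset of face adjacency) is what
reconstructs connected seams.  Tri-junctions are degree-3 nodes after
contraction of degree-2 chains; branch bearings are taken at arc distance
$r$ along each chain (default $2\bar l$ for cracks, $0.2\langle d\rangle$
for trough lines), and the junction angles
$\theta_1 \le \theta_2 \le \theta_3$ (summing to 360°) are the circular
gaps between bearings.  Junctions of degree ≥ 4 or with coincident branch
directions are excluded and counted.

Each junction is the point $(\theta_1, \theta_2)$; the angular spreading
is $\sigma_\theta = \sqrt{A_{1\sigma}/\pi}$ with $A_{1\sigma}$ the area of
the 68%-probability-mass ellipse of a Gaussian fitted to the scatter,
giving $\sigma_\theta = \sqrt{-2\ln 0.32}\,(\det\Sigma)^{1/4}$.  The
quoted "one standard deviation (~68%)" convention is ambiguous in 2D —
the Mahalanobis 1σ ellipse covers only 39% of a 2D Gaussian — so the 68%
mass convention is the default and the Mahalanobis variant sits behind
`ellipse = "mahalanobis1"`.  Junctions are classified by the nearest of
the three archetypes (120,120), (90,135), (90,90) — the Voronoi partition
of the admissible region.  Angle densities use a Gaussian KDE with
reflection at 0° and a seeded bootstrap band; trough-line networks come
from the Voronoi tessellation of the papilla centres (computed by
half-plane clipping), whose unjittered-hexagon limit is exactly the
honeycomb of (120,120,120) junctions.

Two orientation metrics are reported against the local trough direction
(the smaller-|curvature| eigenvector of the height-field Hessian,
finite-differenced on the closed form, undefined at umbilic points):
the *broken-edge* direction — bonds severed by tension — and the
*crack-line* direction — the seam segments.  Under growth both align with
the troughs.  Under shrinkage the broken bonds still align with the local
tension (which follows the trough network), so the seams they form run
*across* the troughs; the crack-line metric is the one that separates the
two protocols.

## Numerical choices and degenerate inputs

* Mesh regularisation is tangential, length-weighted Laplacian smoothing
  plus re-projection (onto the closed-form substrate when available, else
  the closest point of the original mesh), boundary vertices smoothed
  only along the boundary polyline with sharp corners (> 20° turn)
  pinned.  No edge splits or collapses are performed, so topology is
  preserved exactly and a uniform grid is a fixed point; the flip side is
  that on steep surfaces the achievable edge-length uniformity is bounded
  below by the surface's metric anisotropy at the fixed connectivity.
* Relaxation tolerances default to $10^{-3}$ on the maximum nodal force
  and speed (force unit: $k_s \times$ strain), resolving strain to about
  $10^{-3}$ near the breaking threshold.
* Zero-amplitude substrates are legal everywhere and give the documented
  null results (empty trough mask, no fracture under growth).
* Flat hinges have $\theta_0 = 0$; the dihedral sign follows the shared
  edge orientation fixed by the lexicographic edge list, which also fixes
  the deterministic tie-break of simultaneous maximal strains.
* The snapshot used for "3% broken" reporting is reconstructed exactly
  from the event log of a longer run when both use the same increment:
  breaking is sequential and deterministic, so the shorter run is a
  prefix of the longer one.

## Design choices on open ground

The exact discrete energies behind the published model are not specified
in the sources available to this package, so the five terms above are
standard discrete-shell forms stated openly (quadratic hinge penalty
rather than $1-\cos$; per-face area term rather than a true volumetric
term, which has no unique meaning for a single surface; outer-fibre
fracture criterion rather than membrane-only, since pure membrane strain
cannot transmit the bending stresses that the growth mechanism relies
on).  Each term is isolated behind one function so an alternative form is
a local change.  Junction statistics on simulated cracks use the midpoint
projection described above as the bridge from broken mesh edges to the 2D
networks measured on photographs.

## Known limitations

* The growth-versus-shrinkage contrast is partial.  With tangential
  anchoring to the substrate (the fixed-foot tether), residual shrinkage
  tension follows the trough network, so shrinkage bond damage also
  concentrates inside the trough mask and many of its seams still run
  along troughs: at the standard operating point the seam-to-trough angle
  roughly doubles relative to growth (about 40 degrees versus about 20)
  rather than flipping past 45, and the trough-area fraction of broken
  edges barely drops.  A stronger contrast, with seams crossing papillae,
  would require a substrate interaction that permits tangential sliding
  (one-sided contact), a different model from the tether implemented
  here.
* Growth cracks at the 3% snapshot are open seams but rarely meet;
  junction statistics therefore use a matured run (growth continued to
  $h = \langle d\rangle/3$ or 8% broken edges), mirroring the observation
  that crack junctions need time to develop.
* No abrasion, no viscoelasticity, no through-thickness material
  gradient: the innermost, better-hydrated sheets appear only as the
  continuous inner curves of virtual sections, not in the mechanics.
* True dynamic fracture (stress waves, branching instabilities) is out of
  scope: loading is strictly quasi-static.

## Problem sizes

The bundled end-to-end checks run the standard fixture (about 5,000
vertices, 15k edges) through one matured growth run, one half-increment
growth run and one shrinkage run, plus many small analytic fixtures; the
full suite and the reproduction script each complete in tens of minutes
on a single core.
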