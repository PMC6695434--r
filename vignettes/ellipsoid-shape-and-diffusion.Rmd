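---
title: "Protein shape, hydrodynamics and crowded diffusion with ellipshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein shape, hydrodynamics and crowded diffusion with ellipshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ellipshape)
```

## The model

`ellipshape` treats a globular protein as the *ellipsoid of equivalent
steric volume*: the uniform triaxial ellipsoid whose moment-of-inertia
tensor matches that of the protein modelled as solid van der Waals
spheres (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Å; anything else 1.7 Å with
a warning). Each atom contributes weight $(4\pi/3)r_i^3$ and a
solid-sphere term $\tfrac{2}{5}r_i^2$ on the tensor diagonal. With
eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ and the summed
steric volume $M$ acting as the mass, the semi-axes are

$$a = \sqrt{\tfrac{5}{2M}(\lambda_1+\lambda_2-\lambda_3)},\qquad
  b = \sqrt{\tfrac{5}{2M}(\lambda_1+\lambda_3-\lambda_2)},\qquad
  c = \sqrt{\tfrac{5}{2M}(\lambda_2+\lambda_3-\lambda_1)}.$$

Shape is summarized by $\alpha = a/c$ and $\beta$ with
$\alpha^\beta = b/c$: $\beta = 0$ is a prolate spheroid, $\beta = 1$
oblate, and the curve
$\beta_b(\alpha) = (\ln(\alpha+1)-\ln 2)/\ln\alpha$ separates generally
prolate from generally oblate bodies. Note that $\beta_b \to 1/2$ as
$\alpha \to 1^+$ and increases towards 1 with growing $\alpha$ (a fact
the test suite asserts; it follows from l'Hôpital on the formula).

```{r shape}
cl <- make_ellipsoid_cloud(generator_spec(c(30, 20, 10), seed = 7),
                           n_atoms = 2e4)
ell <- steric_ellipsoid(cl)
ell
shape_ab(ell)
```

### Choices worth knowing about

* **Centre for the tensor**: the volume-weighted centroid (weights
  $(4\pi/3)r^3$), consistent with the solid-body analogy.
* **Degenerate eigenvalues** are resolved by a deterministic sign
  convention (first nonzero eigenvector component positive, right-handed
  frame).
* **Volume identity**: for a tensor generated by a continuum solid
  ellipsoid with $M$ equal to its volume, $(4\pi/3)abc = M$ exactly. For
  a discrete cloud the recovered axes match the *filled region*, so the
  ellipsoid volume exceeds the summed atom volume by roughly the inverse
  packing density (~1/0.64); the recovered *shape* is what matters.
* **Calliper scan**: Feret diameters are the min/max axis-aligned
  extents over rotations about x then y in 1° steps on $[0, 90°)$, with
  every atom padded by its vdW radius (a flag disables padding). The
  scan's discretization error bound is $1-\cos(\pi/180) \approx
  0.015\%$.
* **Surface area** uses the Thomsen-type approximation with $p =
  1.6075$ (at most ~1.1% from the exact integral); the isoperimetric
  quotient $36\pi V^2/A^3$ is volume-free and 1 only for spheres.

## Dilute hydrodynamics

Semi-axes are dilated by a stationary hydration layer (2.32 Å without
hydrogens, 2.30 Å with — switchable), and per-axis translational and
rotational constants follow from Carlson symmetric elliptic integrals
$R_F$ and $R_D$, implemented by the duplication algorithm to ~1e-12 and
cross-checked against adaptive quadrature in the tests. Means are
arithmetic over the axes, and the equivalent closed form in
$(\alpha', \beta', r')$ agrees with the per-axis mean to 1e-9 — both
code paths are exercised. Units: Å, K, mPa·s in; cm²/s and 1/s out.

```{r hydro}
lyso <- ellipsoid(23.4, 15.3, 13.9)      # a lysozyme-scale ellipsoid
dilute_diffusion(lyso, dH = 2.3)
hydration_level(lyso, dH = 2.3, mass_Da = 14300)$n_waters
```

Fitting $c\,M^{-1/3}$ to predictions for the modal hydrated shape
($\alpha' = 1.65$, $\beta' = 0.34$, hydrated volume 2.39 Å³/Da, 20 °C,
1.0016 mPa·s) over 40 log-spaced masses between 10 and 1000 kDa gives a
translational prefactor of about 254 in units of $10^{-7}$ cm²/s (about
53 per cube-root residue at 110 Da/residue); the same machinery at 37 °C
with a 0.35 crowding factor gives about 136.

## Crowded self-diffusion

Short-time self-diffusion uses the Tokuyama–Oppenheim form
$D_S^S/D^0 = 1/(1+L(\varphi))$ with $B = (9\varphi/8)^{1/2}$,
$C = 11\varphi/16$; the long-time ratio adds a cage term with strength
$\kappa$ that diverges at the critical volume fraction $\varphi_c$.
`rate_optimum()` maximizes $\varphi\,D(\varphi)/D^0$: the hard-sphere
quadratic model has the closed-form optimum $\varphi_c/3$ (19% at
$\varphi_c = 0.58$).

`fit_phi_c()` estimates $(\varphi_c, \kappa)$ by bounded nonlinear least
squares (Levenberg–Marquardt), initialized at $\varphi_{c,0} = 1.05
\max\varphi$, $\kappa_0 = 2$. The default weighting is *relative*
(weights $1/y^2$, floored at $10^{-3}$): MSD-derived diffusion ratios
carry multiplicative errors and span two decades near arrest, and
unweighted least squares lets the large, least informative low-$\varphi$
points dominate while the near-arrest points that actually locate
$\varphi_c$ contribute nothing. The interface consumes pre-normalised
ratios $D/D^0$, so the fit is invariant to the $D^0$ normalisation by
construction.

## The Gay-Berne simulator

Crowded suspensions are simulated as soft ellipsoids interacting through
$V = 4\epsilon(\zeta^{-12}-\zeta^{-6})$ for $\zeta < \zeta_{cut}$, with
$\zeta = (r-\sigma+\sigma_{\min})/\sigma_{\min}$ and
$\sigma^{-2} = \tfrac12\hat r\cdot H^{-1}\cdot\hat r$. We build $H = A_i
+ A_j$ with $A = R\,\mathrm{diag}(\ell_a^2,\ell_b^2,\ell_c^2)\,R^T$,
which reduces exactly to the uniaxial
$2\ell_\perp^2 I + (\ell_\parallel^2-\ell_\perp^2)(e_ie_i + e_je_je)$
form for spheroids and extends it to the triaxial shapes needed for
collision mapping. The $\ell_k$ are calibrated in closed form so the
pair energy is 1 at face-to-face contact along each axis
($V(2a) = V(2c) = 1$); $\sigma_{\min} = \min_k \ell_k$ as printed in the
field's convention we follow. $\zeta_{cut} = 2^{1/6}$ keeps only the
repulsive branch (forces vanish continuously at the cut), making the
particles soft and purely repulsive.

Reduced units: unit-volume particles, $k_BT = 1$, $\gamma_t = \gamma_r
= 1$, $\delta t = 10^{-4}$. The Brownian integrator is first-order
Euler–Maruyama with isotropic rotational diffusion; the Langevin variant
integrates unit-mass velocities with the same friction (rotation stays
overdamped). Numerical safeguards: $\zeta$ is floored at 0.2 inside the
potential and the *deterministic* drift is capped at $0.25\sigma_{\min}$
per step, so transient deep overlaps during compression relax instead of
ejecting particles; the noise term is never capped, and cap events are
counted and reported as a warning. Neighbour search uses a linked-cell
list rebuilt each step; all randomness flows from R's RNG, so a single
`set.seed` makes runs bit-reproducible.

Protocols: an initial random sequential insertion at $\varphi = 0.05$, a
compression ramp to the target volume fraction (affine box rescale),
equilibration, then production. The desk default is 256 particles with a
$10^4$-step ramp, $10^4$-step equilibration and $10^5$-step production;
the acceptance suite uses $8\times10^3$/$8\times10^3$/$8\times10^4$ at
four volume fractions $\{0.25, 0.35, 0.45, 0.55\}$ (the ladder spans up
to 55%, the regime that carries the $\varphi_c$ information) and three
seeds; the full-scale protocol (8100 particles, $2.5\times10^5$ steps)
is a config override. At the desk scale the sphere fits land near
$\varphi_c \approx 0.56$–0.57 and prolate $\alpha = 1.6$ spheroids
reliably above them — the *ordering* is the desk-scale claim; the
published point values (0.565 and the 0.64 maximum near $\alpha = 1.64$)
belong to the full-scale protocol.

$D_t$ comes from the MSD slope $\langle d^2\rangle/6t$ over a
late-time window (default the upper half of the lag range; free-particle
checks use early windows where the MSD is linear from the origin), with
multiple time origins and particle-block uncertainty; strongly sub- or
super-linear MSDs are flagged.

## Surface cartography

A body-frame surface point is $x = t\cos\theta$, $y =
t\sin\theta\cos\varphi$, $z = t\sin\theta\sin\varphi$ with $t$ the
radial scale that puts the point on the ellipsoid; $\theta$ is measured
from the $a$ axis and $\varphi$ from $b$ towards $c$. Maps are 180×360
grids with pixel centres at half-degrees. Geodesic distances are
computed by an iterative lowest-value expansion over the pixel graph
(8-connected, wrapping in $\varphi$; 8-connectivity was chosen for its
lower metrication error), each step costing the Cartesian distance
between neighbouring pixel-centre surface points — within 2% of great
circles on spheres and ~3% of section arcs on triaxial bodies.

Contact and residue events are deposited as Gaussian spots
$\exp(-g^2/2\sigma^2)$ with $\sigma = 10°$ of arc by default — we read
the source convention "variance 10° arc" as the standard deviation,
flagged here because it is an interpretation. Arc degrees are obtained
by dividing the geodesic length by the local radius $t$ at the deposited
point; a flat-pixel-degree variant is available by flag. Deposits are
additive and not area-weighted (matching the presentation convention; an
area-weighted view can be formed by multiplying by $\sin\theta$, and the
location-independence of total deposited mass on a sphere holds exactly
in that weighted sense).

Collisions in the simulator are *onsets* of contiguous $\zeta < 1$
intervals for a pair — a threshold-crossing definition, chosen because
the soft potential has no unambiguous hard-contact instant. The contact
angles are the body-frame centre-to-centre directions at onset. Dimer
contact centres are found by uniformly shrinking both posed ellipsoids
to external tangency; the Perram–Wertheim contact function $F$ gives the
tangency scale as $s = \sqrt{F}$ in closed form, which we verify by
bracketing the overlap predicate.

```{r dimer}
A <- ellipsoid(1, 1, 1)
B <- ellipsoid(1, 1, 1, centroid = c(1, 0, 0))
dimer_contact_centre(A, B)[c("scale", "angles_A")]
```

## Composition-based shape

Ellipsoid volume scales as $V \approx 203N$ Å³ and area as $A \approx
47N_s$ Å², with $N_s$ estimated from per-type surface propensities
(the packaged propensity table is synthetic and clearly labelled so —
the canonical per-type frequencies are not printed anywhere we can
consume; supply measured values for real analyses). Inverting the area
model gives $\alpha$ from composition alone; the minimum chain length
keeping a 0.55 surface fraction is $36\pi\,203^2/(0.55^3 47^3) = 270$
residues. The binary surface/buried (HP) model puts the modal
composition at $N_s = N/2$; its printed aspect ratios for a 400-residue
chain (1.57/1.66/1.52 for $\beta$ = 0/0.4/1) reproduce here only to
~2–3% because the constants 203 and 47 are rounded — the tests treat
them as approximate checks. Surface residues are defined by fractional
radial extent $m \ge 0.75$ by default (configurable; the underlying
criterion is not stated in the source material, so this is a package
choice made once).

## What the synthetic generator does and does not emulate

`make_ellipsoid_cloud` fills a prescribed triaxial ellipsoid uniformly
at protein-like packing (203 Å³/residue, 8 atoms/residue, C:N:O:S ≈
62:17:20:1), flags one Cα per residue and is deterministic under seed.
It reproduces the *first and second moments* of real structures — which
is exactly what the inertia-tensor pipeline consumes — but has no
backbone connectivity, no secondary structure, no density gradient and
no sequence realism. Passing tests therefore validate the geometry and
the estimators, not biological composition statistics. `make_dimer`
poses two clouds in exact external tangency with ground-truth contact
angles; `make_residue_scalars` plants uniform, c-pole-low (2× contrast)
or radial-gradient (4× core-to-surface) patterns for the mapping
pipeline to recover.

## Numerical notes and limitations

* Carlson integrals: duplication algorithm, relative tolerance ~1e-12;
  domain violations error out rather than returning NaN.
* Root finding for $\alpha(V, A, \beta)$: bracketed on [1, 50],
  tolerance 1e-9; sub-spherical areas are an explicit error.
* The rate optimum uses a $10^{-5}$ grid in $\varphi$; the quadratic
  model's closed form is matched to that resolution.
* No hydrodynamic interactions in the simulator (free-draining): dilute
  $D^0$ is exactly $k_BT/\gamma$, and the short-time Tokuyama reduction
  is not reproduced — $\kappa$ absorbs this in fits, which is why fitted
  $\kappa \ll 2$ at desk scale.
* Anomalous-diffusion models, event-driven hard-particle dynamics and
  packing/unpacking phase-point estimation ($\varphi_F$, $\varphi_M$,
  $\varphi_{MRJ}$) are out of scope; `rate_optimum` accepts a
  user-supplied $\varphi_c(\alpha,\beta)$ surface instead.
* The equirectangular map grid oversamples poles; geodesic costs shrink
  accordingly, so pole-crossing paths stay accurate, but pixel counts
  are not areas.
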