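# ellipshape

Protein shape, hydrodynamics and crowded diffusion via equivalent steric
ellipsoids.

Globular proteins are not spheres: their shapes cluster around an aspect
ratio of ~1.6. `ellipshape` is for structural biophysicists and
molecular modellers who want to quantify that asphericity and trace its
consequences for diffusion and interaction. The package:

* extracts the **ellipsoid of equivalent steric volume** from a PDB
  structure — the uniform triaxial ellipsoid whose inertia tensor
  matches the protein's vdW-sphere model — with semi-axes
  `a = sqrt(5(λ1+λ2−λ3)/2M)` (and cyclic permutations) from the tensor
  eigenvalues, plus calliper (Feret) diameters and the shape
  descriptors `α = a/c`, `α^β = b/c`;
* predicts **dilute-limit translational and rotational diffusion** of
  the hydrated triaxial ellipsoid through Carlson symmetric elliptic
  integrals `R_F`, `R_D` (Perrin-type friction), with a 2.3 Å
  stationary hydration layer and the mass scaling law
  `D_t ≈ 252/M^(1/3) × 1e-7 cm²/s`;
* models **crowded self-diffusion**: short-time
  `D/D0 = 1/(1+L(φ))` and a long-time cage form that vanishes at the
  critical volume fraction `φ_c`, with nonlinear fitting of `φ_c` and
  maximization of the reaction-rate proxy `φ·D(φ)`;
* runs reduced-scale **Brownian/Langevin dynamics of soft Gay-Berne
  ellipsoids** (Rcpp core, cell lists, bit-reproducible under seed)
  with MSD-based diffusion, `φ_c` extraction, and collision-location
  recording;
* builds **θφ surface maps** (180×360) with geodesic Gaussian-spot
  deposition, dimer contact centres by shrink-to-tangency
  (Perram–Wertheim), and residue-value maps;
* predicts **size and shape from composition**: `V ≈ 203N` Å³,
  `A ≈ 47N_s` Å², the inverse of the surface-area model for `α`, the
  270-residue minimum length at a 0.55 surface fraction, and the binary
  surface/buried (HP) model;
* generates **synthetic structures** (ellipsoidal atom clouds, touching
  dimers, residue scalar patterns) so the whole pipeline runs and tests
  without downloading anything.

## Worked example

```r
library(ellipshape)

# a synthetic 30 x 20 x 10 A protein-like atom cloud, ~1200 residues
cl  <- make_ellipsoid_cloud(generator_spec(c(30, 20, 10), seed = 7),
                            n_atoms = 2e4)
ell <- steric_ellipsoid(cl)
ell
#> <equivalent_ellipsoid> a=30.09 b=20.16 c=10.10 A | alpha=2.978 beta=0.633 (oblate)
#>   volume 25662.5 A^3, steric volume M 372128.8 A^3

dilute_diffusion(ellipsoid(23.4, 15.3, 13.9), dH = 2.3)   # lysozyme-scale
#> <hydro_result> T=293.15 K, eta=1.0016 mPa.s, dH=2.30 A
#>   hydrated semi-axes 25.70 / 17.60 / 16.20 A (r'=19.42)
#>   Dt (a,b,c) = 1.147e-06 1.064e-06 1.047e-06 cm^2/s  mean 1.086e-06
#>   Dr (a,b,c) = 2.526e+07 1.837e+07 1.800e+07 1/s     mean 2.054e+07
```

The worked numbers: a 23.4/15.3/13.9 Å ellipsoid (α = 1.69, β = 0.18)
dilated by 2.3 Å of hydration water predicts a mean translational
diffusion constant of 1.09e-6 cm²/s and rotational constant 2.1e7 s⁻¹
at 20 °C in water — in the range measured for lysozyme. The hydration
shell holds ≤ 365 water molecules (`hydration_level()`), consistent with
a monolayer.

Crowding and the reaction-rate optimum:

```r
rate_optimum("quadratic", phi_c = 0.58)$phi_percent
#> [1] 19
```

— the hard-sphere model's `φ D` product peaks at 19% volume fraction,
the cytoplasmic regime. A simulated ladder of volume fractions for one
shape, fitted for its glass point:

```r
cfg <- sim_config(n = 256)
out <- phi_c_pipeline(1.6, c(0.25, 0.35, 0.45, 0.55), cfg, seed = 1)
out$fit
#> <crowding_fit> phi_c = 0.5953 (se 0.0096), kappa = 0.132
```

Prolate spheroids of aspect ratio 1.6 jam later (higher `φ_c`) than
spheres (~0.57 at this reduced scale), so moderately elongated particles
keep diffusing at concentrations where spheres arrest.

## Command line

A thin CLI installs with the package (`exec/ellipshape`):

```sh
ellipshape shape my.pdb          # a,b,c, alpha, beta, class, V, A, quotient
ellipshape diffuse my.pdb --temp 293.15 --visc 1.0016
ellipshape crowd --phi-c 0.64 --kappa 2 --optimize true
ellipshape synth cloud --axes 30,20,10 --seed 1 --out fixture
```

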