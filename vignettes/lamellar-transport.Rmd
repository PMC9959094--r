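---
title: "Modelling molecular transport in lamellar lipid mesophases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling molecular transport in lamellar lipid mesophases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesodiff)
```

## The physical model

A lamellar (L&alpha;) lipid mesophase is a periodic stack of fluid bilayers
alternating with water channels, with lattice parameter $a$ along the stack
normal $z$. A guest molecule (a drug, an amino acid) experiences two
one-dimensional periodic fields:

* a **potential of mean force** $U(z)$, in units of $k_BT$, encoding its
  hydropathy: a tail-region plateau $\Delta U$ ($>0$ hydrophilic, $<0$
  hydrophobic), a head-region barrier or well $\Delta U_b$, and zero free
  energy in bulk water;
* a **local diffusivity** $D(z)$ interpolating from $D_\mathrm{lip}$ inside
  the bilayer to $D_\mathrm{wat}$ in bulk water across a transition layer of
  thickness $w$ of reduced-mobility interfacial water.

Both fields are built from matched parabolic branches so that the value
*and* the first derivative are continuous everywhere — a requirement of the
stochastic integrator, which consumes $dU/dz$ and $dD/dz$. Profiles are
defined on the half period $[0, a/2]$ ($z = 0$ at the bilayer midplane) and
extended by even reflection, so derivatives vanish at both symmetry planes.

Default geometry (`a = 6.65` nm, `l = 2.365` nm, `h = 1` nm, `w = 0.96` nm)
corresponds to a fully hydrated DPPC lamellar phase at 43&nbsp;&deg;C; `w`
is chosen so that $D_\mathrm{wat}$ is reached exactly at the channel centre,
avoiding a derivative discontinuity there. For amino-acid-style tabulated
potentials the conventional lipid length is `l = 2.5` nm with `w = 0.825`
nm. The mobility contrast defaults to $D_\mathrm{lip} = 0.09\,
D_\mathrm{wat}$, and $D_\mathrm{wat} = 0.7$ nm&sup2;/ns unless a molecule's
own value is supplied.

Electrostatics, membrane undulations, anisotropic local mobility and
non-lamellar topologies are outside the model: $U$ and $D$ are
one-dimensional, and the same local $D$ drives the noise in all three
Cartesian directions.

## Brownian dynamics

The overdamped It&ocirc; update with multiplicative noise is

$$
\begin{aligned}
x &\leftarrow x + \sqrt{2 D\,dt}\,\xi_x, \qquad
y \leftarrow y + \sqrt{2 D\,dt}\,\xi_y,\\
z &\leftarrow z - \frac{D}{k_BT}\frac{dU}{dz}\,dt + \frac{dD}{dz}\,dt
  + \sqrt{2 D\,dt}\,\xi_z,
\end{aligned}
$$

with all coefficients evaluated at the pre-step position. The explicit
$+dD/dz$ term is the It&ocirc;-consistent "spurious-drift" correction:
without it a position-dependent $D$ biases the stationary density towards
slow regions ($\rho \propto 1/D$ instead of uniform), and the package keeps
a switch (`spurious_drift = FALSE`) purely as a negative control for this
effect.

Times are measured in the natural unit $\tau = \sigma^2 / D_\mathrm{wat}$
($\sigma = 1$ nm; $\tau \simeq 1.43$ ns for $D_\mathrm{wat} = 0.7$
nm&sup2;/ns). The default timestep `dt = 3e-4` $\tau$ is the largest value
that reproduces the equilibrium distribution of a barrier system of a few
$k_BT$; `validate_timestep()` re-runs that protocol (particles released at
$z = 0$, folded long-run histogram compared against $U$) for any candidate
list, and coarse timesteps fail it by systematically eroding barriers.

Ensembles are pre-equilibrated by inverse-transform sampling of
$e^{-U}$ (`sample_boltzmann()`), making the ensemble stationary from frame
zero. The C++ core uses a counter-seeded xoshiro256++ generator with a
ziggurat normal sampler and one substream per particle, so trajectories are
bit-reproducible for a given seed and independent of particle ordering.
Trajectories are never folded; density diagnostics fold $z$ internally.

## Observables

`compute_msd()` implements fixed-origin ensemble averages
$\mathrm{MSD}_\parallel = \langle (x-x_0)^2 + (y-y_0)^2 \rangle$ and
$\mathrm{MSD}_\perp = \langle (z-z_0)^2 \rangle$; no sliding time origin is
used because the pre-equilibrated ensemble is stationary, so fixed-origin
averages are unbiased. At long times
$\mathrm{MSD}_\parallel = 4 D_\parallel t$ and
$\mathrm{MSD}_\perp = 2 D_\perp t$.

Perpendicular dynamics shows three regimes — free diffusion at short times,
a subdiffusive dip while barriers localize the particle, and effective
diffusion once many periods have been crossed. `local_exponent()` estimates
$d\ln \mathrm{MSD} / d\ln t$ by windowed log-log regression (default 0.5
decades; plain centred differences are far too noisy for stochastic MSDs).

**Fit-window rule.** `fit_long_time()` fits the final window in which the
local exponent stays at 1 within a tolerance band. A fixed band of 0.05
is only meaningful for noiseless input: the local exponent of an
$N$-particle ensemble MSD fluctuates with amplitude of order
$\sqrt{2/(\mathrm{dim}\,N)}$ (about $\pm 0.1$ at $N = 500$), so the band is
widened to `max(tol, noise_mult * sqrt(2/(dim * N)))`. Detection is
one-sided (the subdiffusive transient approaches slope 1 from below; upward
excursions are noise), the window may reach at most 1.5 decades below the
final time (so shallow undetected transients cannot contaminate the fit),
and the window's overall log-log slope must itself lie in the band,
otherwise no estimate is returned — a run stuck in the subdiffusive regime
yields a diagnostic, not a number. The usual run-length heuristic
($\max \mathrm{MSD}_\perp \ge 100$ nm&sup2;) is promoted to an explicit
convergence flag; estimates from shorter runs are returned but marked
lower-confidence.

## Closed-form theory

* **Partition coefficient.** $10^{\log P} = (\int_0^l e^{-U} dz / l) \,/\,
  (\int_l^{a/2} e^{-U} dz / (a/2 - l))$, computed by adaptive quadrature of
  the full expression (no assumption that $U = 0$ in water).
* **Lateral transport.** $D_\parallel$ equals the thermal average
  $\int e^{-U} D \,dz / \int e^{-U} dz$ — exact here, because the lateral
  drift vanishes and the stationary lateral MSD grows with the equilibrium
  mean of $D$ at every instant. Substituting the two-phase decomposition
  and $\bar D = (D_\mathrm{wat} + D_\mathrm{lip})/2$ for the transition
  layer gives the closed form
  $$D_\parallel = \frac{D_\mathrm{lip}\,(l\,10^{\log P} + w/2) +
  D_\mathrm{wat}\,(a/2 - l - w/2)}{l\,10^{\log P} + a/2 - l},$$
  which is exact for the piecewise toy model (its water region has $U = 0$
  and a symmetric transition layer) and an excellent approximation for
  realistic profiles. Its limits are $D_\mathrm{lip}$ for strong
  hydrophobes and the mean water-region diffusivity (below
  $D_\mathrm{wat}$!) for strong hydrophiles.
* **Perpendicular transport.** The exact long-time coefficient of 1-D
  diffusion in a periodic medium,
  $D_\perp = \left[\langle e^{U}/D\rangle \langle e^{-U}\rangle\right]^{-1}$
  (period averages), the classical two-average result. The package uses it
  as a deterministic oracle: to cross-validate every stochastic estimate,
  and to budget run lengths before simulating (the time needed for
  $\mathrm{MSD}_\perp$ to reach a target is known in advance). By the
  Cauchy–Schwarz inequality $D_\perp \le D_\parallel$ for this family, with
  equality only for constant profiles.
* **Effective transport.** Micron-scale domains are orientationally
  disordered, so release experiments see
  $D_\mathrm{eff} = \tfrac23 D_\parallel + \tfrac13 D_\perp$. Above
  total barriers of ~5 $k_BT$, $D_\perp$ is exponentially suppressed
  (Arrhenius decay with rate just under 1 per $k_BT$; the closed form gives
  0.91–0.99 across the studied ranges) and
  $D_\mathrm{eff} \simeq \tfrac23 D_\parallel$, fully analytic given
  $(\log P, D_\mathrm{wat})$ and geometry. `drug_transport()` evaluates
  both the lateral closed form and the $\tfrac23$-weighted version for a
  table of molecules; the shipped reference values coincide with the
  *lateral* form (no $\tfrac23$ factor), and both columns are always
  reported rather than silently preferring either.

## The &alpha;-rescaling extrapolation

Systems with barriers of tens of $k_BT$ cannot be simulated directly.
Scaling $U \to \alpha U$ with $\alpha < 1$ lowers every barrier
proportionally; $\ln D_\perp(\alpha)$ is then fitted linearly in $\alpha$
and extrapolated to $\alpha = 1$. This presumes the activated (Arrhenius)
regime, where $\ln D_\perp$ is close to linear in barrier height. The
deterministic oracle quantifies the model error: for a toy 8 $k_BT$ head
barrier, a ladder with scaled barriers of 4.8–7.2 $k_BT$
($\alpha \in \{0.6, \dots, 0.9\}$) extrapolates to within ~5% of the exact
value, while a ladder at 2.4–4.8 $k_BT$ ($\alpha \in \{0.3,\dots,0.6\}$)
overshoots by a factor ~2 because $\ln D_\perp$ is still curved there.
Ladders should therefore keep $\alpha \times$ (total barrier)
$\gtrsim 5\ k_BT$ whenever affordable; when a deep ladder is unavoidable,
the extrapolated $D_\perp$ is so small that its contribution to
$D_\mathrm{eff}$ is negligible anyway.

## Synthetic data and what passing tests show

`generate_fixtures()` produces the package's own test inputs: toy profiles
sampled on finite grids (interpolation round trips), "amino-acid-like"
tabulated potentials — a tail plateau plus a head barrier or well with a
small smooth modulation, the architecture of residue transfer profiles in
phospholipid bilayers — and the reference drug table. These synthetic
potentials exercise the identical pipeline (tabulated loader &rarr; BD
&rarr; fits &rarr; closed forms) as externally derived profiles, but they
are idealized: real potentials of mean force carry statistical noise,
asymmetries and fine structure, and real systems have anisotropic,
state-dependent local mobility that the one-dimensional $D(z)$ model cannot
represent. Passing tests therefore validate the *transport machinery given
the profiles*, not the profiles themselves.

For titratable molecules, the charged and neutral potentials are combined
as their pointwise minimum (`combine_charged_pmfs()`); grid nodes within a
0.05 nm window of each branch crossing are dropped and the interpolating
spline bridges the kink, restoring a continuous derivative while shifting
barrier heights by well under 0.05 $k_BT$.

## Numerical choices

* Quadratures: `stats::integrate` per smooth segment, relative tolerance
  1e-9; profile breakpoints are supplied as segment boundaries.
* Tabulated potentials: periodic cubic spline on the mirror-extended data
  (which forces zero slope at both symmetry planes); extrema located on a
  10&#8201;001-point half-period grid and refined by local optimization.
  At second-derivative jumps of a piecewise-parabolic source the spline
  derivative carries an $O(\Delta z)$ local error — values are accurate to
  ~1e-3 $k_BT$ on a 200-point grid, derivatives to ~1e-2 away from
  junctions.
* Integrator lookup tables: 8193 points on the half period, linear
  interpolation (interpolation error is negligible against the timestep
  discretization error).
* Equilibrium histograms: 60 bins on the half period, expected weights by
  per-bin quadrature of $e^{-U}$, count-weighted offset alignment, and
  deviations assessed where $U \le 6\ k_BT$ with tolerance 0.15 $k_BT$.

## Study scales

The shipped tests and the acceptance script run reduced-scale versions of
the reference studies, sized so the full suite completes on one CPU:
ensembles of 200–2000 particles (instead of $10^3$–$10^4$) and run lengths
budgeted per system from the closed-form $D_\perp$ so that
$\mathrm{MSD}_\perp$ reaches 45–60 nm&sup2; (instead of 100), capped at a
few thousand $\tau$. Arrhenius studies use barrier ladders of 5–8 $k_BT$;
statistical tolerances in the tests (10–15% on individual stochastic
coefficients, 0.1 on fitted decay rates) correspond to roughly three
standard errors at these ensemble sizes.

## Known limitations

* $D(z)$ is isotropic: parallel and perpendicular local mobilities are
  known to differ near interfaces; quantitative lateral predictions for
  strongly bound molecules depend on this simplification.
* The $\log P$ closed form inherits the sharp lipid/water partition and
  the symmetric transition-layer assumption; both are exact for the toy
  model and mild for realistic profiles with $U \approx 0$ in water.
* The effective-medium $\tfrac23$/$\tfrac13$ weighting assumes randomly
  oriented domains with no grain-boundary resistance.
* Constant-pH effects are reduced to the min-combination of charged and
  neutral profiles; dynamic protonation is not simulated.
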