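---
title: "Pseudopod splitting and the amoeboid correlated random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudopod splitting and the amoeboid correlated random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudowalk)
```

## The model

Amoeboid cells such as *Dictyostelium* move by extending pseudopodia.
Tracking data show that pseudopod formation is highly ordered: most
pseudopodia *split* off near the tip of the current one, at an angle of
roughly 55 degrees, preferentially alternating right and left; the rest
form *de novo* on the cell body, in essentially random directions.
`pseudowalk` implements the resulting five-parameter movement model:

| parameter | meaning | units | typical (5 h starved WT) |
|-----------|---------|-------|-----|
| `lambda_p` | pseudopod size (tip displacement per event) | µm | 5.2 |
| `s` | splitting fraction (vs. de novo) | – | 0.86 |
| `a` | probability that consecutive splits alternate R/L | – | 0.77 |
| `phi` | splitting angle to the previous pseudopod | degrees | 55 |
| `sigma_phi` | SD of the realised pseudopod angle | degrees | 27.8 |

Each simulated step draws four uniform deviates: split vs. de novo
(`s`); alternate vs. repeat side (`a`, applied when the previous event
was a split, otherwise a fair coin); the de novo side coin; and the de
novo direction.  The projected direction (previous direction ± `phi`
for splits, uniform for de novo) is then perturbed by von Mises noise
with `kappa = 1/sigma_phi^2` (sigma in radians).  Right is clockwise,
i.e. a negative angular increment; the convention is fixed
package-wide.  `sigma_phi = 0` is handled as a deterministic point
mass, giving a perfect zig-zag when `s = a = 1`.

Two deliberate simplifications: de novo directions are exactly uniform
(real cells show a slight deficit towards the previous direction), and
time is step-indexed — pseudopod interval fluctuations only rescale the
time axis, so a constant synthetic 30 s interval (13 s growth phase) is
used when event tables are exported.  Simulated de novo steps that
happen to fall near the previous direction are *not* re-annotated as
splits; the two misclassification fluxes approximately cancel.

## Dispersal theory

Over pairs of steps the alternating zig-zag reduces to a correlated
random walk with effective step size $\lambda = \lambda_p\cos(\phi/2)$
and mean squared displacement

$$\langle d^2(n)\rangle \;=\; \lambda^2\!\left[
  n\,\frac{1+\gamma}{1-\gamma} \;-\;
  \frac{2\gamma(1-\gamma^{\,n})}{(1-\gamma)^2}\right],$$

where $\gamma$, the correlation factor, is the mean cosine of the turn
angle.  Considering the seven kinds of step pairs (RL/LR straight
ahead with weight $a$, RR/LL turning $2\phi$ with weight $1-a$, and the
three de novo–containing pairs averaging to zero) gives the pair
correlation factor

$$\gamma_{\mathrm{pair}} = s^2\,[\,a + (1-a)\cos 2\phi\,]\;
  E[\cos(\varepsilon_1+\varepsilon_2)],$$

and per step $\gamma_{\mathrm{step}} = \sqrt{\gamma_{\mathrm{pair}}}$,
which with the small-noise surrogate $E[\cos\varepsilon]\approx\cos\sigma_\phi$
yields the closed form

$$\gamma_{\mathrm{step}} = s\,\cos(\sigma_\phi)\,
  \sqrt{a + (1-a)\cos 2\phi}.$$

```{r closed-forms}
wt5 <- pseudopod_model(5.2, 0.86, 0.77, 55, 27.8, name = "WT 5h")
c(gamma_step = gamma_step(wt5), gamma_pair = gamma_pairs(wt5),
  lambda = step_size(5.2, 55), theta = turn_angle(gamma_step(wt5)))
```

**Noise expectation conventions.**  Three are exported, because they
genuinely differ at the noise levels of real cells and the literature
is loose about which is meant:

* `cos_sigma_approx(sigma)` — the surrogate $\cos\sigma$ used in the
  closed form above (default of `gamma_step()`);
* `expected_cos_vmd(kappa)` — the exact von Mises mean cosine
  $I_1(\kappa)/I_0(\kappa)$;
* `expected_cos_wrapped_normal(sigma)` — $e^{-\sigma^2/2}$.

For the *pair* noise, `gamma_pairs()` defaults to the exact expectation
for the sum of the two independent per-step von Mises noises,
$E[\cos(\varepsilon_1+\varepsilon_2)] = (I_1/I_0)^2$ at
$\kappa = 1/\sigma_\phi^2$: that is what the simulator actually
produces, and it keeps $\gamma_{\mathrm{step}}^2$ and
$\gamma_{\mathrm{pair}}$ within 5% of each other for
$\sigma_\phi \le 30^\circ$.  The older approximation that replaces the
summed noise by a *single* von Mises of doubled variance
(`noise_model = "single_vmd"`, $\kappa = 1/(2\sigma_\phi^2)$) deviates
from the closed form by ~9% already at $\sigma_\phi = 28^\circ$ — the
sum of two von Mises variables is not von Mises, and the discrepancy is
entirely due to that substitution; the wrapped-normal variant
($e^{-\sigma^2}$) is exact under a wrapped-normal noise model.  The
per-step default remains the $\cos\sigma$ form because that is the
closed form the per-strain predictions quote; at
$\sigma_\phi = 46.5^\circ$ (the star-shaped mutant) the three
conventions separate by a few hundredths and none is singled out as
"the" value.

## Fitting the MSD

`fit_crw()` fits the closed-form MSD by least squares over all supplied
lags, unweighted, with `gamma` searched on $(-0.99, 0.9995)$ by
golden-section to machine tolerance.  Two variants:

* `lambda` fixed — the protocol for *observed* centroid dispersion,
  where $\lambda = \lambda_p\cos(\phi/2)$ is identified independently
  from pseudopod geometry and only $\gamma$ is free;
* `lambda = NULL` (both free) — the protocol for *simulated* ensembles.
  The model is linear in $\lambda^2$ at fixed $\gamma$, so $\lambda$ is
  profiled out analytically.  This variant is required for internal
  consistency: a pure de novo walk (`s = 0`) is Brownian with step
  $\lambda_p$, not $\lambda_p\cos(\phi/2)$, and fixing the wrong step
  size would masquerade as spurious persistence ($\gamma \approx 0.13$
  rather than 0).  For split-dominated walks the fitted step size
  converges to $\lambda_p\cos(\phi/2)$, which is how the pair-walk step
  size is verified by simulation.

$\gamma$ is reported unclamped and flagged (`out_of_range`) when it
falls outside $[0, 1)$.  The fit validates its input: negative or
decreasing ensemble MSD values are rejected rather than silently
absorbed.

```{r pipeline}
w <- simulate(wt5, nsim = 2e4, seed = 1, n_steps = 30)
fit <- fit_crw(ensemble_msd(w))
coef(fit)
```

The ensemble MSD is the squared displacement from the origin averaged
over trajectories — deliberately *not* the time-averaged MSD, matching
the definition behind the closed form.  The default problem size for
the end-to-end reproduction (`run_table1_reproduction()`) is 100,000
trajectories of 30 steps, the published ensemble size and the number of
pseudopodia a cell extends in a 15-minute recording; the examples here
use smaller ensembles, and 20,000 trajectories already estimate
$\gamma$ to about ±0.01.

A note on reproducing the published per-strain Monte Carlo values: the
source text describes the simulated-ensemble fit once as estimating
both $\lambda$ and $\gamma$ and once (in the table footnote) as fixing
$\lambda$ like the observed-data fit.  The two protocols differ by up
to 0.08 in $\gamma$ for weakly persistent strains.  This package uses
the both-free protocol for ensembles, for the internal-consistency
reason above; with it, the fitted $\gamma$ agrees with the closed-form
$\gamma_{\mathrm{step}}$ to within 0.03 for every strain with
$\sigma_\phi < 30^\circ$.

## Directional displacement

The expected displacement projected on the first step direction is the
geometric series $\lambda(1-\gamma^n)/(1-\gamma)$, saturating at
$\lambda/(1-\gamma)$ — about 15 µm (three pseudopod lengths) for the
strongly persistent 5 h starved parameters:

```{r directional}
directional_displacement(c(1, 5, 10, Inf), step_size(5.2, 55), 0.70)
```

## Circular statistics

Angles are degrees in $(-180, 180]$ at every public interface and
radians internally; `kappa = 1/sigma^2` (sigma in radians) is the
package-wide concentration convention.  Von Mises sampling uses the
Best–Fisher rejection algorithm, vectorised; `sigma = 0` short-circuits
to a point mass.  The distribution of splitting angles is fitted by
`fit_bimodal_vmd()`, an equal-weight two-component von Mises mixture
with modes at $\pm\phi$ sharing one concentration, maximised by
bounded quasi-Newton from a grid of 8 mode starts (ties broken by
likelihood, then smaller $\phi$); an all-equal-magnitude input takes a
degenerate `sigma_phi = 0` branch.  The wrapped Cauchy density is
provided for fit comparison only — the data it was rejected for were
von Mises shaped — and no wrapped Cauchy *fitting* is offered.

## The cell-shape statistic

`shape_psi()` quantifies how far an outline deviates from an ellipse.
The outline (a simple closed polygon, ~150 nodes in tracker output) is
bracketed between an inscribed and a circumscribed ellipse; an
intermediate ellipse is interpolated between them and positioned so
that the cell area outside it ($O$) equals the ellipse area outside the
cell ($I$); the statistic is $\Psi = (O+I)/T$ with $T$ the cell area.
$\Psi$ is 0 for an ellipse, approaches 2 for extreme shapes, and was
observed up to 0.92 in real cells.

Construction choices (the source describes the ellipses only verbally):

* the base ellipse is a direct algebraic least-squares conic fit to the
  vertices; inner and outer ellipses scale it about its centre by the
  largest factor that keeps it inside the polygon (checked on the
  boundary subsampled 4× per edge, then verified at 512 sampled
  ellipse points, nudging down by 0.5% steps if sampling missed a
  concavity) and the smallest factor covering all vertices;
* interpolation is parameter-wise linear in centre and semi-axes, with
  orientation along the shortest angular path modulo 180° — a
  convention, since radial-field interpolation would be equally
  consistent with the verbal description;
* boolean areas clip the polygon against the ellipse discretised at 256
  vertices (Sutherland–Hodgman, valid because the ellipse is convex);
* the balancing parameter solves $O(t) = I(t)$ by bisection (60
  iterations, tolerance $10^{-3}\,T$).  Since
  $O - I = T - \mathrm{area}(\mathrm{ellipse}_t)$ identically, the
  residual is monotone in $t$ and a sign change is guaranteed when the
  inner/outer areas bracket $T$; if they do not, the minimiser of
  $|O-I|$ is reported with a warning flag.

$\Psi$ is invariant under translation, rotation and uniform scaling to
about $10^{-3}$ (discretisation), and on the synthetic star family it
grows monotonically with spike amplitude:

```{r shape}
sapply(c(0, 0.15, 0.3), function(A)
  shape_psi(make_outline("star", spike_amplitude = A))$psi)
```

The angular noise of a strain tracks its shape irregularity; the
empirical line `sigma_from_psi(psi) = 37.6 * psi + 22.8` degrees is
shipped as a *generative* coupling for building shape-consistent
synthetic strains.  Reproducing that regression from synthetic cells is
out of scope — it is an empirical property of real mutants, not of the
generator.

## Synthetic data

All inputs the package consumes can be generated in code, seeded:

* `make_outline()` — exact ellipses, sinusoidally modulated stars
  (radius $r(\theta) = r_0(1 + A\sin k\theta)$, chosen so that $\Psi$
  is monotone in $A$), and smoothly perturbed ellipses; defaults are
  150 nodes and 7 × 4.5 µm semi-axes, a typical amoeboid cell scale.
* `make_event_table()` — tracker-style event records from the
  simulator.  By default the split-angle noise is decomposed into two
  independent wrapped-normal components, the tangent orientation at the
  emergence site (34.5 ± 24.9°) and the pseudopod-to-tangent angle
  (89.1 ± 13.3°), so the synthetic tangent columns carry realistic
  statistics and the total angular SD is their quadrature sum
  ($\sqrt{24.9^2+13.3^2} = 28.2^\circ$).  This decomposition encodes
  the mechanistic picture that most angular noise comes from local
  shape (tangent) variability, with a smaller contribution from
  imperfect perpendicularity of outgrowth.
* `table1_strains()` — the published per-strain parameter values,
  exactly as printed, with the reference correlation factors.

What passing tests on these fixtures do *not* show: the generators make
wrapped-normal or von Mises noise by construction, have no measurement
error, no pseudopod-annotation ambiguity, no temporal overlap of
pseudopodia and no centroid-versus-tip distinction.  In real data the
centroid turns less sharply than the pseudopod tip (the rear of a cell
tracks like the rear wheels of a car), which raises the observed
centroid correlation factor ~15% above the pseudopod-level prediction —
the package predicts pseudopod-level persistence and leaves the
centroid correction as this documented note.

## Numerical choices

* Angle normalisation to $(-180, 180]$ everywhere; exact periodicity of
  the densities.
* `besselI(..., expon.scaled = TRUE)` throughout, so likelihoods and
  expectations do not overflow at large concentration.
* Simulation is vectorised across trajectories from a single seeded
  stream (four uniforms per trajectory per step, plus the noise draws,
  in a fixed order): a given `(seed, n_traj, n_steps)` is exactly
  reproducible.  Per-trajectory RNG substreams were considered and
  dropped — base R has no spawnable substream API and nothing here is
  parallel.
* `gamma = 1` is a dedicated ballistic branch of the closed-form MSD;
  `gamma_step()` raises a domain error when
  $a + (1-a)\cos 2\phi < 0$ (possible only near $\phi = 90^\circ$ with
  small $a$, outside the biological range).
* Degenerate geometry (duplicate vertices, self-intersection, zero
  area) is rejected at `cell_outline()` construction with specific
  messages.

## Known limitations

* The closed-form $\gamma_{\mathrm{step}}$ uses the $\cos\sigma$
  surrogate; above $\sigma_\phi \approx 30^\circ$ it diverges from the
  simulated ensembles (by ~0.07 at 46.5°), which is intrinsic to the
  approximation, not a bug.
* The inscribed/circumscribed ellipses are concentric scalings of one
  fitted base ellipse, not the true maximal inscribed ellipse; exact
  for elliptical cells, slightly conservative for strongly asymmetric
  shapes.
* Pseudopod growth dynamics within a step, multi-pseudopod overlap,
  chemotactic bias, and centroid mechanics are out of scope.
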