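---
title: "Traveling waves of orientation selectivity in a laminar neural field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling waves of orientation selectivity in a laminar neural field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarwave)
```

## The model

`laminarwave` implements a two-layer continuum model of primary visual
cortex. The deep layer carries an orientation-independent activity
field $u(x,t)$ with strong, retinotopically organized recurrent
excitation $w_d$; the superficial layer carries an orientation-labelled
field $v(x,\theta,t)$, $\theta \in [-\pi/2, \pi/2)$, organized as a
continuum of hypercolumn ring networks with local (within-hypercolumn)
connections $w_{loc}(\theta)$ and weak long-range horizontal connections
$w_s(x)\,w_{hoz}(\theta)$ that link similar orientations in different
hypercolumns. Vertical feedforward drive ($\gamma_d$, deep to
superficial) and orientation-averaged feedback ($\gamma_s$, superficial
to deep) couple the layers:

$$\tau_d \partial_t u = -u + w_d * f_d(u)
  + \gamma_s \int f_s(v)\, d\theta,$$
$$\tau_s \partial_t v = -v + w_{loc} \ast f_s(v)
  + w_s * w_{hoz} \ast f_s(v) + \gamma_d f_d(u),$$

with sigmoidal rates $f_j(u) = 1/(1 + e^{-\eta_j (u - \kappa_j)})$ or
their high-gain Heaviside limit $H(u - \kappa_j)$, under which the
interface (threshold-crossing) analysis is exact. The scientific claim
the package is built to reproduce and probe: the deep layer alone
supports a traveling activity front; the front drives each superficial
ring through a bump-forming instability; and the *weak horizontal
connections are what turn a sequence of independently tuned bumps into
a spatially coherent traveling wave of orientation selectivity* — with
feedback to the deep layer changing the wave's shape but not its speed.

### Closed-form layer: fronts and bumps

For the exponential kernel $w_d(x) = \bar w_d e^{-|x|/\sigma_d} /
(2\sigma_d)$ the Heaviside front speed is explicit
(`front_speed_exponential()`):

$$c = \frac{\sigma_d}{2\tau_d}\Big(\frac{\bar w_d}{\kappa_d} - 2\Big)
  \quad (\kappa_d < \bar w_d/2), \qquad
  c = \frac{\sigma_d}{2\tau_d}
  \frac{\bar w_d/\kappa_d - 2}{\bar w_d/\kappa_d - 1}
  \quad (\bar w_d/2 < \kappa_d < \bar w_d),$$

and no front exists for $\kappa_d \ge \bar w_d$. For arbitrary
integrable kernels the speed solves
$\kappa_d = |c|^{-1}\int_0^\infty e^{-y/|c|} W_d(\mathrm{sign}(c) y)dy$
with $W_d(y) = \int_y^\infty w_d$; `front_speed_implicit()` brackets and
bisects this monotone relation (the right-hand side decreases from the
kernel mass to zero as $c$ sweeps from fast-leftward to fast-rightward,
so the root is unique and the solver is robust rather than fast — every
evaluation is a cheap 1D quadrature). Restoring units, the speed scale
is $\sigma_d/\tau_d$: 10 cm/s for a 1 mm kernel range and a 10 ms
relaxation time (`speed_scale_cm_per_s()`).

On the ring, stationary bumps of half-width $\Delta$ under constant
drive $I$ satisfy $W(2\Delta) = \kappa_s - I$, where $W$ is the odd
primitive of the ring kernel, with stability iff $W'(2\Delta) < 0$, and
profile $V(\theta) = W(\theta + \Delta) - W(\theta - \Delta) + I$. (Some
presentations print the profile with a plus sign between the two $W$
terms; since $W$ is odd, only the difference form satisfies
$V(\pm\Delta) = \kappa_s$, and that is what `bump_solve()` returns.)
`bump_solve()` scans $W(2\Delta)$ on a dense grid (resolution `1e-4`)
and polishes each sign change with `uniroot()`, so arbitrary ring
kernels are admissible without symbolic work; `operating_conditions()`
evaluates the three regime conditions (down state unique without drive;
bump exists under drive; no down-state coexistence under drive) from
grid extrema of $W$ for the same reason.

Behind the full laminar wave the relevant ring kernel is the *combined*
kernel $w_{loc} + w_{s,0} w_{hoz}$, because the horizontal connections
sample the (asymptotically uniform) active region. Its stable half-width
$\Delta_0$ fixes the asymptotic deep up state
$w_{d,0} + 2\gamma_s\Delta_0$ (`feedback_up_state()`): feedback raises
the plateau by the orientation-integrated superficial rate, but since
the superficial threshold crossing lags the deep interface ($z_0 < 0$),
it never touches the deep interface dynamics — the Heaviside wave speed
is *exactly* feedback-invariant, which the simulations reproduce to
machine precision in the interface trajectory.

### The four-region anatomy of the wave

In the frame $z = x - ct$ the superficial profile decomposes into
quiescent, queuing, integrating and bump regions
(`classify_regions()`). The queuing region is the mechanistically
important one: populations ahead of the deep front receive only weak,
orientation-peaked horizontal input from the active bumps behind the
front, of magnitude at most $w_{s,0} w_{hoz,0}$ (`queuing_bound()`;
0.064 for the canonical parameters, comfortably below
$\kappa_s = 0.5$). These sub-threshold pre-bumps inherit the phase of
the wave — the drive $\Omega_{hoz}(\theta - \theta_0, \Delta)$ peaks at
the bump centre $\theta_0$ (`omega_hoz()`) — so when the deep front
arrives and forces each ring through threshold, the emerging bump is
already phase-aligned. Without horizontal connections there is no
queuing and each activated ring picks an orientation at random from
whatever perturbation is present.

## Numerical scheme

Forward Euler in time with spatial convolutions computed as Fourier
products on the periodic grid and orientation convolutions as periodic
trapezoidal sums (on a uniform periodic grid the Fourier product *is*
the trapezoidal convolution sum, exactly; the unit tests verify this
against direct summation to 1e-12). Sampled kernels are wrap-periodized
by summing a few image displacements, so no kernel mass is lost on the
circle. In 2D the anisotropic horizontal kernel
$w_A(r, \theta_m) = w_s(|r|) A(\arg(r) - \theta_m)$ depends on the
receiving orientation, so one spatial kernel per orientation channel is
tabulated and transformed once (`build_kernel_bank()`); the removable
$\arg(0)$ singularity is closed with the angular mean of $A$ (1 in both
modes, preserving the isotropic limit).

Numerical conventions worth stating:

* **Heaviside at threshold**: $H(0) = 1$, so the active set is closed
  and indicator algebra is well defined. The interface analysis never
  evaluates exactly at threshold; this is purely a tie-break.
* **Stability guard**: the steppers reject
  $\Delta t > 0.1\,\min(\tau_d, \tau_s)$.
* **Interfaces** are located by linear interpolation between the
  bracketing nodes of the rightmost down-crossing; speeds are
  least-squares slopes over a fit window with the transient discarded
  (`estimate_speed()`).
* **Phases** are per-site argmaxima over $\theta$ refined by a
  three-point quadratic fit on the periodic axis, reported modulo
  $\pi$; flat slices are undefined (`NA`) and near-ties are flagged
  multimodal. Orientation statistics double the angles
  (`circ_variance_pi()`), the standard device for axial data.
* **Effective horizontal range**: the compact-support construction of
  the region boundaries is reconciled with Gaussian kernels by taking
  $L$ as the radius containing all but $10^{-4}$ of the kernel mass,
  and a numeric floor of $10^{-6}$ separates "quiescent" from "queued"
  activity. Both are package conventions, not model content.
* **Periodic wrap**: a step initial condition on a circle has two
  edges, so a second, mirror-image front exists through the boundary;
  diagnostics windows in the tests exclude it. `run_1d()` warns when
  the tracked interface comes within $3\max(\sigma_d,\sigma_s)$ of the
  boundary (where Gaussian tails reach the percent level).

## Default parameters and fixtures

The canonical coupled parameter set (fixture `fig6_wave`, used by most
experiments) is: Gaussian kernels with $w_{d,0} = 2$,
$\sigma_d = 0.1$, $w_{s,0} = 0.1$, $\sigma_s = 1$; ring kernel
$w_{loc} = (-1 + 2\cos 2\theta)/\pi$ (stored as $w_1 = 2$, i.e.
$2w_2$ with $w_2 = 1$ in the alternative convention) and
$w_{hoz} = (1 + \cos 2\theta)/\pi$; $\kappa_d = \kappa_s = 0.5$;
$\gamma_d = \gamma_s = 1$; $\tau_d = \tau_s = 0.1$; sigmoid gain
$\eta = 10$ (Heaviside for the interface-theory checks). Under these
values all three operating conditions hold, the combined-kernel bump
has $\Delta_0 \approx 0.812$ rad, the deep up state with feedback is
$\approx 3.62$, and the Gaussian-kernel deep front moves at
$c \approx 0.92$ (caption units).

The ring-model demonstration fixture (`fig5_ring`) uses the stronger
Mexican hat $(-2 + 8\cos 2\theta)/\pi$, which supports bumps even
without external drive.

## What the noise model is and is not

The bilaminar model needs orientation-dependent symmetry breaking:
a ring driven through threshold by a perfectly uniform input converges
to an orientation-uniform state hugging the threshold and never tunes.
The package's perturbation is the minimal one — independent, zero-mean
uniform noise per $(x, \theta)$ node injected once at $t = 0$, seeded
and reproducible (`add_orientation_noise()`). Two consequences of this
choice matter for interpreting results:

* With Heaviside rates and forward Euler, a one-shot perturbation
  smaller than the per-step activity increment near threshold
  (roughly $\gamma_d \Delta t/\tau_s \approx 10^{-2}$ at the defaults)
  is wiped out: every orientation node crosses threshold in the same
  step and the ring stays exactly uniform. The Heaviside noise
  experiments therefore use amplitude $10^{-2}$. The smooth-rate 2D
  experiments break symmetry through the continuously graded drive and
  work with $10^{-4}$.
* Real cortical fluctuations are continuous in time and spatially
  correlated; a one-shot white perturbation is a deliberately
  structureless stand-in. Passing tests show the *mechanisms*
  (queuing-mediated coherence, decoherence without horizontal
  connections, seed-dependent synchrony) — not quantitative noise
  robustness of real tissue.

## 2D experiments and domain sizes

The 2D model (`run_2d()`) reproduces three phenomenologies:

* **Anisotropic plane wave** (fixture `fig9_plane_aniso`,
  $96^2 \times 24$ on a $7.5$-wide domain): with
  $A(\psi) = 1 + \cos 2\psi$ the interior phase locks to $\pi/2$ —
  orientation orthogonal to the propagation direction, parallel to the
  front — with circular variance below $10^{-5}$ at the defaults.
* **Anisotropic target wave** (fixture `fig10_target_aniso`,
  $64^2 \times 24$ on a $4$-wide domain, seed disc $r_0 = 0.1$): the
  phase converges to the angular pattern $\phi(r) = \arg(r)$ to a few
  $10^{-3}$ rad.
* **Isotropic runs** (fixtures `fig9_plane_iso`, `fig10_target_iso`,
  $48^2 \times 16$ on a compact $2.56$-wide domain): phases become
  synchronous within a run but the common value is a function of the
  noise seed alone.

The isotropic domain choice deserves a note. With weak horizontal
coupling, phase alignment spreads diffusively and is slow: on a domain
many $\sigma_s$ wide, independently seeded bump phases survive for tens
of time units. Global synchrony on a practical time horizon requires
the horizontal footprint to span the domain — the regime in which each
hypercolumn effectively interacts with every other through the
periodized kernel. The package therefore requires only
`extent >= 2 * sigma_s` for
the (wrap-periodized) kernel bank and uses the compact domain for the
isotropic fixtures, while the anisotropic fixtures — whose phase
selection is geometric, not diffusive — run on larger domains.

Shift–twist symmetry (joint rotation of retinotopic space and
orientation labels) is an exact symmetry of the discrete model for
quarter turns on a square grid with an even number of orientation
channels, and `shift_twist_check()` verifies equivariance of full runs
to $10^{-10}$.

## Problem sizes, tolerances, and what is deliberately out of scope

The default test and acceptance runs use $\Delta x = 0.02$,
$\Delta\theta = \pi/50$, $\Delta t = 0.002$ in 1D and the 2D grids
listed above — coarser than the finest grids the model was developed
at, chosen after verifying that the reported observables are already
converged there (simulated front speeds within 1% of the closed form,
simulated bump half-widths within $2\Delta\theta$ of $\Delta_0$, phase
errors at the $10^{-3}$ rad level). Halving $\Delta t$ halves the
field-level error, as expected for forward Euler.

Out of scope by design: formal stability analysis of fronts
(Evans-function machinery), continuation of the wave in the sigmoid
gain, the slow-time phase-coupling reduction, traveling pulses (which
need adaptation), distinct excitatory/inhibitory populations, explicit
pinwheel orientation-preference maps, and hallucination/Turing or
binocular-rivalry extensions.
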