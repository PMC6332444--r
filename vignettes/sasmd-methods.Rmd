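---
title: "Self-adaptive steered molecular dynamics on synthetic binding landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-adaptive steered molecular dynamics on synthetic binding landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasmd)
```

## The method

Steered molecular dynamics (SMD) mimics an atomic-force-microscopy pulling
experiment: the ligand's position $R(t)$ is coupled to a constraint point
moving with velocity $v$ along a unit direction $\mathbf{n}$ through a
harmonic spring of stiffness $k$,

$$U_\mathrm{pull} = \tfrac{1}{2} k \left[\, v t - (R(t) - R(0)) \cdot
\mathbf{n} \,\right]^2 .$$

The signed scalar pulling force logged each step is $k x$, the spring
stiffness times the extension $x = v t + x_\mathrm{off} - (R - R_\mathrm{ref})
\cdot \mathbf{n}$ (projection on the current direction; it can be negative if
the ligand overtakes the constraint). Forces are averaged in consecutive
non-overlapping windows of $T = 1$ ps, and the **rupture force** is the
maximum windowed average observed during dissociation — the proxy for how
strongly the complex resists unbinding.

In conventional SMD (C-SMD) the direction $\mathbf{n}$ is fixed at the start.
The self-adaptive variant (SA-SMD) instead treats the pulling direction as a
decision variable: whenever more than $t_0 = 5$ ps have passed since the last
optimization *and* the trailing 1-ps average force exceeds a cut-off $f_0$
(default 250 pN), the run is checkpointed and the direction re-optimized by
minimizing the trial average force

$$\min_{\varphi,\,\theta} \; \bar F(t, T, \varphi, \theta), \qquad
-\pi \le \varphi \le \pi,\; 0 \le \theta \le \tfrac{\pi}{2},$$

where $(\theta, \varphi)$ are nutation and precession angles about the
*initial* direction $\mathbf{n}_0$ (so all candidates stay in
$\mathbf{n}_0$'s hemisphere; `recenter = TRUE` measures them about the current
direction instead), and each candidate is scored by restarting a short
segment of length $T$ from the checkpoint. All candidates restart from the
same random-number-generator state (common random numbers), so they are
compared on identical noise realizations; the adopted direction is then
re-simulated from the checkpoint on the main stream — trial segments are
never reused. Across a switch the spring's accumulated extension is carried
over (`x_offset`), which keeps the force magnitude continuous and protects
the trigger and the optimizer's objective from artificial spikes.

The inner optimizer is a multi-population genetic algorithm with an
information-entropy coupling. $m = 16$ populations share the initial design
space; each generation, the per-population best fitnesses $F_j$ are mapped to
occurrence probabilities $p_j$ (a softmax of standardized, negated
fitnesses by default; a rank rule is available), the entropy
$H = -\sum_j p_j \ln p_j$ is recorded, and every population's box is narrowed
around its own best member:

$$E(K) = (1 - p_j)\, E(K{-}1), \qquad
d_i^{\mathrm{lo}}(K) = \max\{ d_i^* - \tfrac12 (1-p_j) E(K),\,
d_i^{\mathrm{lo}}(0)\},$$

and symmetrically for the upper bound — the clamps guarantee no individual is
ever evaluated outside the initial design space. The bi-objective
$(\min \sum_j p_j F_j,\ \min H)$ is scalarized with weights $(w_1, w_2)$;
over the probability simplex the scalarized objective is linear plus a
concave entropy term, so its minimum sits on a vertex — all mass on the
population with minimal $F_j$ — which is why the scalarized problem and
$\min_j F_j$ share their optimal solution (this is verified by an
enumeration test). Within each population we use real-coded individuals,
tournament selection (size 2), blend crossover, Gaussian mutation with
$\sigma$ proportional to the current extent, and one elite.

### Choice of the probability rule

The simplex constraint alone does not fix $p_j$. The default is
$p_j \propto \exp(-z_j/\tau)$ with $z_j$ the standardized best fitnesses and
$\tau = 0.5$: it is invariant to shifting and rescaling the objective (the
engine's forces are hundreds of kJ mol$^{-1}$ nm$^{-1}$, so scale invariance
matters), exactly uniform for equal fitnesses, and strictly decreasing in
$F_j$. Being scale-invariant it cannot send $p \to (1, 0)$ for two
populations however large their gap — at $m = 2$ the better population
receives $\approx 0.94$ — which we consider the right behaviour for a
scale-free rule; the rank-based alternative
$p_j = 2(m - r_j + 1)/(m(m+1))$ is one configuration switch away.

## The surrogate system

The package replaces the all-atom protein–ligand complex with a point ligand
on a smooth, closed-form binding-pocket surface (energies kJ/mol, lengths nm,
times ps; 1 kJ mol$^{-1}$ nm$^{-1}$ = 1.66054 pN). The surface is built from
four ingredients:

* an isotropic Gaussian **binding well** of depth $D$ (the analogue of the
  binding free energy magnitude) and width $\sigma_w = 0.25$ nm;
* a radial **barrier shell** $s(\rho) = x e^{1 - x}$, $x = (\rho/\rho_b)^2$,
  peaking at $\rho_b = 0.8$ nm, whose height is angularly modulated: each
  exit **channel** direction carries its own barrier height, the **rim**
  (250 kJ/mol) applies between channels;
* tube-like channel geometry: the effective squared angular width is
  $w^2 + r_t^2/\rho^2$, so the exits converge and merge at the pocket bottom
  (as channels of real pockets do) and tend to the angular width $w$
  outward;
* a **pocket wall**: high energy (200 kJ/mol at its peak) outside the
  channels over the pocket's radial range, vanishing at the pocket bottom
  and in the far field.

The standard demo pocket has two channels: a moderate groove
(45 kJ/mol) along the conventional pulling axis $+z$ — so a fixed-direction
pull is laterally trapped, as in a corrugated protein exit — and a soft
channel (12 kJ/mol) rotated 45° away. The binding-site **separation** used
for termination is the distance from a 0.8 nm spherical envelope; runs end
when it exceeds 0.6 nm.

The pocket wall deserves a note, because it is what makes the surrogate
behave like a pocket rather than a fairground. In an early open-well design
the direction optimizer discovered that it could relieve spring tension
indefinitely by dragging the ligand back and forth through the well core —
each re-optimization harvested a core-diameter of extension, pinning the
force just above $f_0$ and preventing dissociation altogether. That is not a
bug of the optimizer but a real property of greedy windowed-force
minimization in any cavity with free room: yielding always beats climbing
over one window. A binding pocket, however, is a dead-end cavity whose only
free room is the exit channels; the wall term implements exactly that, and
with it the force ratchets up between re-optimizations until the soft
channel's thermally assisted escape becomes accessible.

Residual relief cycles remain (the tube itself has finite width), and they
produce a genuinely SA-SMD-like phenomenology: dissociation with
re-optimization takes two to four times longer than C-SMD on the same seed,
along a more tortuous path, at a distinctly lower rupture force.

## Engine and numerics

The ligand follows overdamped (inertialess) Langevin dynamics, Euler–Maruyama
discretized: $\Delta r = (f/\gamma)\,\Delta t + \sqrt{2 k_B T \Delta t /
\gamma}\, \xi$ with $\Delta t = 0.002$ ps and $\gamma = 100$
kJ mol$^{-1}$ nm$^{-2}$ ps. With the standard well curvature
($\approx 800$ kJ mol$^{-1}$ nm$^{-2}$) the relaxation time
$\gamma/\kappa \approx 0.13$ ps is far below the 5 ps optimization interval,
so windowed forces probe the landscape, not the integrator. The discrete
stationary variance of an Euler–Maruyama harmonic well exceeds $k_BT/\kappa$
by a factor $1/(1 - \kappa \Delta t/2\gamma)$; the engine tests choose
$\kappa \Delta t / \gamma = 0.0125$ so this bias (0.6%) is far below the
resolution of the Kolmogorov–Smirnov check at $n = 10^5$ thinned samples.

Randomness comes from R's generator; a simulation state carries its own
saved RNG state, so a checkpoint is the triple (position, time, RNG state)
and restoring it reproduces the subsequent trajectory bit-exactly. Time is
accumulated as $t \mathrel{+}= \Delta t$ inside the compiled loop so that a
run split at checkpoints performs the identical float-operation sequence as
an unsplit run. At $T = 0$ K no random numbers are drawn. Landscape energy
and gradient are analytic (the gradient is finite-difference-verified in the
tests); the angular direction $u = d/\sqrt{\rho^2 + \varepsilon^2}$ is
softened with $\varepsilon = 10^{-5}$ nm so the form is smooth at the
center.

Windows are non-overlapping and aligned to pulling segments; a trailing
partial window is dropped. Rupture ties break to the earliest window. The
trigger's "trailing window" is the mean of the last $T/\Delta t$ raw samples
of the current segment, updated every step, with a strict inequality on the
elapsed time.

## Experimental designs and their parameters

All defaults follow the standard protocol: $k = 200$ kJ mol$^{-1}$ nm$^{-2}$,
$v = 0.002$ nm/ps, $T = 1$ ps, $t_0 = 5$ ps, $f_0 = 250$ pN, 0.6 nm cut-off,
$m = 16$, 100 ps equilibration, 2 fs steps. The in-run GA budget is
deliberately small (16 populations × 4 individuals × 3 generations = 192
trial segments per optimization); the standalone `ga_config()` defaults are
larger.

* **Trigger-force sweep** (`run_sweep`, `cutoff_force`): $f_0 \in \{400, 350,
  300, 250, 200\}$ pN with C-SMD as the $f_0 = \infty$ reference. Lower
  triggers fire earlier and more often; the measured rupture force decreases
  with $f_0$ and flattens once the soft channel's escape force is reached.
* **Pulling-rate sweep** (`pulling_rate`): 0.002 vs 0.005 nm/ps. The escape
  over the soft barrier is thermally activated, so faster loading leaves
  less time for assisted escape and raises the rupture force.
* **Mode comparison** (`compare_modes`): paired C-SMD/SA-SMD runs per seed.
* **Family runs** (`run_family`): families share all geometry and vary only
  the well depth over 20–60 kJ/mol (`reference_energy` $= -D$). Because the
  members span a ~3× force range, a single absolute trigger would never fire
  for weak binders or pin strong ones at $f_0$; with `f0_fraction` the
  trigger is calibrated per member to a fraction (0.75 in the shipped
  experiments) of its own C-SMD rupture force, measured by one calibration
  run — the same practice as tuning the cut-off force on a reference complex
  before a family study, transferred to a heterogeneous family. Four repeats
  per member give means and standard errors (sample SD over $\sqrt{n}$), and
  the correlation report regresses mean rupture force on reference energy
  (negative slope = deeper wells resist more).

Problem sizes in the shipped tests and acceptance script were chosen to keep
a full run on one CPU comfortable: 5 seeds per condition, `max_time` 4000 ps
(3000 ps in family runs), trajectory stride 50 steps. These are package
choices, not method constants; `controller_config()` exposes all of them.

## What the synthetic generator does and does not emulate

The generator reproduces the structural facts the method exploits: a bound
minimum, walled exits with heterogeneous barriers, an easiest escape
direction that deviates from the initial pulling direction, and a tunable
well depth standing in for experimental binding free energy. It does not
emulate solvent friction anisotropy, ligand rotational degrees of freedom,
induced fit, multiple binding poses, or atomic granularity — so passing
trends here show the *algorithm* behaves as described on a landscape with
the right topology, not that it reproduces any particular complex's pN
values. Quantities reported in pN are on the surrogate's force scale;
they happen to be comparable to protein–ligand rupture forces because the
landscape parameters are physically plausible, but no quantitative
correspondence is claimed.

Two surrogate-specific behaviours are worth restating. First, any trigger
below the conventional rupture force lowers the measured rupture somewhat
even on an isotropic pocket, because re-optimization cycles relieve tension;
the "no advantage available" control in the tests therefore sets the trigger
near the conventional rupture force. Second, dissociation *times* under
SA-SMD are longer than C-SMD for the opposite reason — relief cycles stretch
the approach to rupture — which matches the tortuous-pathway phenomenology
of the method.

## Limitations

* The greedy windowed-force objective is myopic; it finds force-relieving
  directions, which on open geometries need not be escape directions. The
  pocket wall mitigates, not removes, this.
* The hemisphere constraint about a fixed $\mathbf{n}_0$ (the literal
  reading) cannot express reversals; `recenter = TRUE` lifts this but makes
  the trajectory direction a random walk over optimizations.
* The probability rule, scalarization weights, and genetic operators of the
  entropy GA are under-determined by the algorithm's published description;
  the defaults here are documented choices, all exposed in `ga_config()`.
* Euler–Maruyama at 2 fs is accurate for the shipped landscapes
  ($\kappa \Delta t/\gamma \ll 1$) but not checked for user landscapes with
  much stiffer walls; halve `dt` if `wall_height`/`tube_radius` are pushed
  far beyond the defaults.
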