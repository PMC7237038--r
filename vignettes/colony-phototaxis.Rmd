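---
title: "Modelling collective phototaxis in cyanobacterial colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collective phototaxis in cyanobacterial colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanotaxis)
```

## The model

Colonies of gliding cyanobacteria such as *Synechocystis* respond to the
direction of incident light: cells crawl toward (or, under UV, away from) a
source, pile up at the colony rim, and then escape through dense finger-like
projections. `cyanotaxis` implements an agent-based model of this behaviour
with three ingredients.

**Light-biased headings.** Each cell is a disc of radius $R$ at position
$X_i = (x_i, y_i)$. Per time step it picks a heading $\theta_i^t$: with
probability $p_k$ it heads exactly along the bearing $\Theta_k$ of source $k$
(per-source bearings and probabilities are fixed at $t = 0$ from the colony
centre; intensity is uniform within a colony), otherwise uniformly at random
on $[0, 2\pi)$. The chosen heading enters the dynamics as a propulsion force
$G_i^t = f_0(\cos\theta_i^t, \sin\theta_i^t)$. Under several sources two
integration scenarios are implemented:

* *stochastic switching* — the cell commits to one source per step, taking
  branch $k$ with probability $p_k$ and a random heading with probability
  $1 - \sum_k p_k$;
* *vector integration* — the cell heads along the direction $\Theta_{vec}$
  of $\sum_k p_k(\cos\Theta_k, \sin\Theta_k)$ with probability equal to the
  norm $p_{vec}$ of that sum, otherwise at random. With exactly cancelling
  sources ($p_{vec} = 0$, e.g. equal sources at $\pm 90^\circ$) every move
  is random.

Negative phototaxis replaces each directed heading by $\Theta_k - 180^\circ$.
Cells carry a wavelength-sensitivity tag and perceive only matching sources.

**Pili contact forces.** Each cell has $m$ type-IV pili of reach $\ell$.
Every step, each cell $j$ attaches to $\min(m, |N_j|)$ targets drawn
uniformly without replacement from its in-reach neighbours $N_j$
(centre-to-centre distance $\le \ell$), and exerts on target $i$ the force
$K(D_{ji})(\cos\theta_{ji}, \sin\theta_{ji})$ with
$$K(D) = \bigl(1 + k_1(\tanh(k_2(D - 2R)) - 1)\bigr)/m .$$
The kernel is a soft core: repulsive below contact $D = 2R$ (exactly zero at
contact for $k_1 = 1$) and saturating to an attractive plateau $1/m$ at long
range, so the force a cell receives from $n$ attackers is bounded by $n/m$.
Attachments are redrawn every step, and no reaction force acts on the puller
(the update writes forces only on targets; a `reciprocal` switch adds
Newtonian reactions for experimentation).

**Slime and overdamped motion.** Cells deposit polysaccharide slime on a
square lattice (spacing $R$): each step, the lattice point nearest a cell's
centre gains $S_{rate}$, capped at $S_{max}$; slime never decays or
diffuses. Motion is overdamped,
$$X_i^{t+1} = X_i^t + (G_i^t + F_i^t)/\gamma_i^t , \qquad
  \gamma_i^t = \gamma_0 S_0 / S^t(r, c),$$
with $S^t(r,c)$ read at the lattice point nearest the time-$t$ position. All
positions are read at time $t$ and committed in parallel; deposition then
happens at the new position (a `deposit_premove` switch moves it before the
commit — the ordering is not fixed by the physics, and post-move matches the
convention that the slime map reflects where cells are). On bare ground
($S = 0$) friction is infinite and the displacement is exactly zero; this is
what transiently traps cells at the colony rim, where slime must build up
before fingers can escape.

## Parameters

| name | meaning | default | unit |
|------|---------|---------|------|
| `n_cells` | cells per colony, $N$ | 500 | – |
| `radius` | cell radius $R$ (the length unit) | 1 | length |
| `rho` | colony areal density $N R^2 / R_{col}^2$ | 0.1 | – |
| `ell` | pilus reach $\ell$ | 4 | $R$ |
| `m` | pili per cell | 4 | – |
| `gamma0` | baseline friction, $1/(0.1R)$ | 10 | step / $R$ |
| `k1`, `k2` | kernel shape | 1, 2 | – |
| `s_rate` | slime deposited per cell per step | 0.1 | slime |
| `s0`, `s_max` | initial in-colony slime, cap | 1, 1 | slime |
| `f0` | propulsion magnitude | 1 | force |
| `p_photo` | directed-move probability | 0.05 | – |
| `n_steps` | run length | 40000 | steps |

$S_0$ and $S_{max}$ are not constrained by the published parameter table;
the package default $S_0 = S_{max} = 1$ starts the colony interior
saturated, which makes the friction bound tight: $\gamma \ge \gamma_0$
everywhere and for all time, so $f_0/\gamma_0 = 0.1R$ per step is a true
maximum speed, attained by isolated cells on saturated slime from $t = 0$.
Both remain configuration knobs.

With `p_photo = 0.05` the colony front advances at roughly
$p \cdot f_0/\gamma_0 \approx 0.005\,R$/step, i.e. about $200 R$ beyond the
rim over a $4\times10^4$-step run. The slime lattice therefore has to be
sized to the planned run length: the `colony_config()` default is a
$300\times300$ lattice (adequate up to roughly $10^4$ steps for a centred
$N = 500$ colony), presets default to $700\times700$, and a cell reaching
the lattice edge raises an error rather than wrapping or clipping.

**Calibration.** Matching the model's maximum speed ($0.1R$/step) against
the measured gliding speed of ~0.1 µm/s for cells of radius ~1 µm gives
`calibrate_dt(0.1, 1, 0.1)` = 1 s per step; `steps_to_hours(1e5, 1)` ≈ 27.8 h,
the scale over which finger formation is observed experimentally.

## Numerical choices

* **Angles** are radians in $[0, 2\pi)$ internally, degrees in user-facing
  constructors, with the compass convention E $= 0^\circ$, N $= 90^\circ$.
* **Nearest lattice point** rounds each axis separately; exact half-spacing
  ties round toward $+\infty$. The slime disc laid down at initialisation is
  inflated by half a lattice diagonal so that every in-disc cell starts over
  slimed ground (pure rounding would strand a few rim cells on bare points).
* **Randomness** flows exclusively through R's global RNG: every entry point
  takes a `seed`, and the compiled loop draws through the same stream in a
  documented order (per step: one branch and one angle uniform per cell in
  index order, then the attachment-selection draws per puller in index
  order, consumed only when a cell has more than `m` neighbours). A run is
  therefore a pure function of (configuration, seed); the pure-R reference
  step `step_state()` reproduces the compiled loop bit for bit, which the
  test suite asserts.
* **Neighbour search** uses spatial binning with bin width $\ell$ and is
  exact — the tests compare it against a brute-force all-pairs oracle.
* **Parallel update**: forces and slime reads use only time-$t$ positions;
  relabelling cells (with relabelled draws) permutes the result exactly.
* **Multiple colonies** are independent systems on separate lattices with
  per-colony substreams derived from the master seed.

## Trajectory analysis and the integration-mode classifier

The headline scientific use of the model is the contrast between colony
morphology and single-cell trajectories. At matched source geometry the two
integration scenarios produce statistically indistinguishable colony shapes
(finger counts and orientations), but the pooled distribution of per-step
movement angles differs qualitatively: switching gives one peak per source;
vector integration gives a single peak at the resultant bearing, fading to
uniform as opposing sources cancel.

`step_angles()` extracts per-interval movement bearings from a trajectory
log. For classification and rose plots the interval should be a **single
time step**: over longer windows a switching cell mixes directed moves
toward *both* sources, so the window-averaged displacement points at the
bisector just as vector integration does, and the signature washes out.
(Longer intervals are supported for coarse drift summaries; they are not
used for mode discrimination.)

`classify_mode()` fits two mixture models by maximum likelihood with the
source bearings held fixed and only the mixing weights and a shared von
Mises concentration $\kappa$ free: one von Mises component per source plus a
uniform component (switching), versus a single component at the vector-sum
bearing plus uniform (vector). Fixing the bearings sidesteps label switching
and lets $\kappa$ absorb the blur contributed by pili forces and friction.
The label is assigned by AIC rather than raw likelihood: with exactly
cancelling sources the vector model degenerates to the uniform density,
which is nested in the switching mixture, so an unpenalised comparison would
call uniform data "switching" through overfitting alone. The raw
log-likelihood difference is reported as the margin; in the single-source
limit the two models coincide and the margin hovers near zero.

`finger_metrics()` segments cells beyond the rim along the light bearing
into fingers by sorting transverse coordinates and splitting at gaps
exceeding one cell diameter (`gap_threshold = 2R`, the smallest physically
meaningful gap; the split is strict, so a gap exactly equal to the threshold
does not split). Width is the transverse extent plus one cell diameter;
separation is the mean adjacent-centre distance. On full-length
single-source runs the width:separation ratio comes out near 1, matching
what colony images show.

## What the generator emulates — and what it does not

Simulated colonies reproduce the qualitative experimental phenomenology:
rim aggregation before egress, fingers directed at (or away from) sources,
finger size growing with intensity, mixed-wavelength colonies sorting toward
their respective sources. The model omits receptor-level signalling,
three-dimensional structure, slime decay and diffusion, pilus
extension–retraction dynamics, cell growth and division, and shading of one
colony by another. Passing tests therefore validate the implementation of
this idealised dynamics, not the biology beyond the regimes the model was
built to mirror.

## Problem sizes used in the tests

The unit tests run seconds-scale simulations (tens of cells, $10^2$–$10^3$
steps) against exact oracles. The end-to-end checks use the full published
conditions where the quantity demands it: finger geometry uses five
$N = 500$, $4\times10^4$-step runs; the morphology-versus-trajectory
discrimination uses ten seeds per integration mode at $10^4$ steps with
per-step trajectories of 100 cells and $10^5$ pooled angles per run, sizes
at which the classifier margin is already decisive (hundreds to thousands
of log-likelihood units).

## Known limitations

* The lattice must be pre-sized to the run length (no dynamic growth).
* `classify_mode()` assumes the source geometry is known; it does not
  estimate bearings.
* Finger segmentation is one-dimensional in the transverse coordinate; it
  can merge fingers that overlap in projection onto the axis orthogonal to
  the light bearing.
* With more than two sources of unequal wavelength the per-cell decision
  table treats visibility as a hard match on the wavelength tag; graded
  action spectra are out of scope.
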