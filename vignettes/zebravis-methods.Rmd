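---
title: "zebravis: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zebravis: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`zebravis` simulates zebrafish swimming in a bounded square arena by a
stochastic, vision-based decision rule. This vignette documents the model
and its assumptions, the parameters that matter, the numerical choices,
the synthetic-data generator used in place of experimental recordings, and
the known limitations — in enough detail that a maintainer could re-derive
every design decision.

## The decision model

Agents live on a two-dimensional plane inside a square tank (default side
1.2 m) and update synchronously every `dt` seconds (default 1/3 s, one
decision per tail-beat). Each update draws, per agent and in id order, one
speed and one heading:

* The **speed** is an independent draw from the instantaneous speed
  distribution of the applicable regime — there is deliberately no speed
  autocorrelation or speed regulation in this model; the focus is the
  directional decision.
* The **heading** is drawn from a circular probability density over the
  body-frame angle $\theta \in [-\pi, \pi]$ ($\theta = 0$ keeps the
  current heading), assembled from von Mises ("circular Gaussian")
  components.

The density has three ingredients:

1. **Baseline / wall following.** Far from walls, von Mises$(0, \kappa_0)$
   with $\kappa_0 = 6.3$ — forward swimming with moderate angular noise.
   Within the wall-interaction distance $d_w = 0.05$ m the density becomes
   an equal-weight two-component mixture centred on the two body-frame
   directions parallel to the nearest wall, with $\kappa_w = 20$: the
   agent follows the wall in either direction. Nearest wall ties (e.g. at
   a corner) break deterministically in the order N, E, S, W.
2. **Stimulus mixtures.** Every congener (and every floating spot) whose
   centroid bearing lies inside the 270° visual field contributes a
   von Mises component centred on its bearing. Component weights are the
   captured **solid angles** normalised within each stimulus kind —
   closer or broadside-on fish loom larger and attract more probability
   mass. The concentrations default to $\kappa_f = \kappa_s = \kappa_w =
   20$ (a deliberate reduction of the parameter space), but all four
   concentrations remain independently configurable.
3. **Global mixture.** The baseline and the per-kind mixtures combine as a
   convex combination weighted by $\alpha^* A_{Tf}$ and $\beta^* A_{Ts}$
   (total captured solid angle times a per-steradian weight). $\alpha^*$
   and $\beta^*$ switch between off-wall and near-wall values
   ($\alpha_0 = 55$, $\alpha_W = 20$; $\beta_0 = 0.15$, $\beta_W = 0.01$).
   When a scenario contains both fish and spots, the singly-fitted weights
   are divided by $w_F = 2$ and $w_S = 9$, giving the jointly fitted
   $\alpha_0 = 27.5$ and $\alpha_W = 10$.

The mixed-condition division is applied per *scenario* (whenever both
stimulus kinds are enabled in the configuration), not per time step
depending on what is currently visible: the division factors were fitted
on whole experiments in which both stimulus kinds were present, so the
scenario-level reading matches how the values were obtained.

A useful emergent property of the mixture form is the choice/compromise
transition: two widely separated, equally sized stimuli produce a bimodal
density (the agent commits to one side), while stimuli closer than a
critical separation merge into a single mode aimed between them. The test
suite locates this transition by bisection on the mode count.

## Perception geometry

Stimuli are perceived as the solid angle they capture on a unit sphere
centred on the focal fish, with azimuth 0 ahead, positive azimuth to the
left (counter-clockwise from above) and elevation measured from the
swimming plane.

* The fish body is a six-vertex polyhedron with the bounding dimensions of
  an adult zebrafish (length 0.035 m, width 0.01 m, height 0.01 m): a nose
  vertex at the head position, four corner vertices at $\pm$width/2 and
  $\pm$height/2 placed 40% of the body length behind the nose, and a tail
  vertex at the full length. Only the bounding dimensions are
  biologically constrained; the 40% station is our choice of a minimal
  six-vertex shape with a forward centre of area.
* A stimulus' projected boundary is reduced to its four extremal
  projections (min/max azimuth relative to the stimulus' circular-mean
  azimuth, min/max elevation), which form a spherical quadrilateral; the
  quad is split along a diagonal into two spherical triangles, and each
  triangle's solid angle is its spherical excess computed from the side
  arcs by L'Huilier's theorem. For a disc-shaped spot the four points are
  the nearest, farthest, leftmost and rightmost rim points. Degenerate
  views (a tail-on fish collapses two extremes onto one vertex) reduce
  the quad to a triangle whose excess is still well defined; the
  user-facing `quad_solid_angle()` instead reports user-supplied
  coincident-vertex quads as degenerate (area 0, with a warning).
* The field of view is 270°, all-or-nothing on the centroid bearing
  (boundary inclusive); perception range is infinite and nothing is
  occluded. Agents may overlap (no body collisions); the engine simply
  skips geometrically degenerate percepts of co-located agents.

The four-point reduction underestimates the full projected silhouette (it
inscribes a "diamond" in the projected bounding region, roughly half its
area for a broadside fish). This affects both calibration and simulation
consistently, so the fitted per-steradian weights absorb the scale.

## Kinematics and boundaries

The sampled body-frame angle is added to the world heading; the agent then
moves `speed * dt` along the new heading. A displacement that would leave
the arena is truncated $10^{-4}$ m inside the boundary with the heading
kept: on the next update the agent is inside the wall-interaction band, so
the wall-following density takes over. This truncation rule (rather than
reflection or resampling) is the simplest boundary that leaves the
decision model in charge of wall behaviour.

Speed regimes: in a homogeneous tank a single distribution (mean 0.07,
sd 0.03 m/s); with spots present, the regime is selected each step by the
agent's current position — outside spots (0.09 ± 0.06 m/s) or under a spot
(0.03 ± 0.02 m/s), i.e. fish rest under shade. Draws use a normal
distribution truncated at zero, sampled by inverse transform on the
conditional CDF; truncation shifts the means upward by about 1% (0.07
regime) to 9% (0.03 regime) relative to the nominal parameters, which the
analysis tolerances account for. An empirical sample pool can replace any
regime's parametric family.

## Numerical choices

* **Angular grid**: 721 nodes over $[-\pi, \pi]$ (0.5° steps), both
  endpoints included so the trapezoid rule integrates the full circle.
  All component densities are analytically normalised; products of this
  smoothness and grid density keep the trapezoid mass within $10^{-6}$ of
  1, which the tests assert for every produced density.
* **CDF and sampling**: cumulative trapezoidal integration, renormalised
  to end exactly at 1; headings are drawn by linear interpolation of the
  inverse CDF at a uniform draw, with ties in flat regions resolved to the
  left node. The von Mises components make the density strictly positive,
  so the CDF is strictly increasing in practice.
* **Bessel function**: $I_0$ is computed by direct series summation,
  terminating when a term falls below $10^{-12}$ of the running total;
  tests cross-check against `base::besselI`.
* **Spherical excess**: L'Huilier's theorem from the three side arcs, with
  the product under the square root clamped at 0 for near-degenerate
  triangles; the user-facing function validates the spherical triangle
  inequalities, while the engine-internal path treats violations within
  rounding as flat (zero excess). Tests verify agreement with the
  independent Girard excess (interior angles from tangent-vector
  geometry) to $10^{-9}$ over 1000 random triangles.
* **Determinism**: one RNG stream per run, seeded from the configuration;
  per step each agent consumes exactly one speed draw and one direction
  draw in id order, so runs are bit-identical under a fixed seed (a
  frozen checksum regression-tests this).
* **Problem sizes in the test-suite** were chosen to finish on a single
  CPU while leaving comfortable statistical margins: e.g. the group
  cohesion check uses three replicates of 20 simulated minutes with 10
  agents, and concentration-recovery checks use $10^5$–$10^6$ samples.

## The synthetic reference generator

No experimental recordings ship with the package, so the analysis and
fitting modules are exercised against synthetic trajectories
(`generate_reference()`) built to carry the measured statistical
structure: per-step von Mises$(0, 6.3)$ heading increments, regime-split
speeds as above, positions recorded at 1 s.

Wall handling in the generator needs care. The three-point speed estimator
$v_t = |P(t+1) - P(t-1)| / (2\,\Delta t)$ measures chord lengths; any
boundary rule that bends or truncates paths deflates it. Plain truncation
leaves walkers jammed against walls (the majority of samples collapse
towards zero), so the generator instead (i) reflects displacements
specularly, preserving walked path length, and (ii) applies a
wall-alignment bias: within 0.15 m of the wall the walker is about to hit
(measured along its heading, excluding a wall it is already hugging), the
heading rotates towards the nearest wall-parallel direction with strength
ramping from 0 at the band edge to 1 at the wall, with corner ties broken
towards open water. This emulates the smooth thigmotaxis of real fish;
near-wall and corner chords stay nearly straight and the configured speed
statistics survive. The bias is a statistical fixture of the generator,
not a mechanistic claim; setting `wall_bias = 0` recovers a pure
reflecting random walk.

Residual estimator biases worth knowing about (all reproduced by the
tests): turning at $\kappa = 6.3$ shortens chords by about 2%; truncation
of the speed distribution at zero lifts means by 1–9%; conditioning
under-spot samples on a full three-frame stencil inside a 0.1 m disc
selects slower walkers, depressing the under-spot conditional mean by
roughly 8%. Net effect: the homogeneous-condition estimator recovers the
configured 0.07 m/s mean within about 2%, and the outside/under speed
ratio lands near 3.2–3.4 against the nominal 3.0 — hence the 2.4–3.6
acceptance band used for the ratio.

What the generator does **not** emulate: tracking noise, identity
switches, freezing bouts (beyond what the truncated normal produces near
zero), speed autocorrelation, or genuine wall/spot preference dynamics.
Passing the pipeline-closure tests therefore shows estimator and fitting
correctness on data with the right first-order structure, not validity of
the behavioural model against real fish.

## Calibration protocol

* `fit_kappa()` bins turning angles (72 bins, 5°) and minimises the sum of
  squared differences to the theoretical von Mises density over a
  $\kappa$ grid with step 0.1. The theoretical density is **averaged over
  each bin** rather than evaluated at the bin centre: a histogram
  estimates the bin average, and the centre-value shortcut biases
  $\kappa$ down by about 0.3 at $\kappa = 20$ with 5° bins (it is
  negligible at 6.3). With the bin-averaged form, self-recovery is exact
  to one grid step at both 6.3 and 20 with $10^6$ samples.
* The basic-swimming concentration is fitted on turning samples taken at
  least 0.30 m from every wall — the position at the sample's central
  frame decides inclusion. Requiring the whole three-frame stencil to be
  interior instead subtly selects against straight segments (which exit
  the interior window sooner) and biases $\kappa$ low by a few percent in
  a 1.2 m tank.
* `grid_search()` runs the forward model over a Cartesian parameter grid
  with fixed replicate seeds (default 3), averages replicate statistics,
  normalises each statistic to unit mass and sums squared differences
  with equal weights — the objective is invariant to statistic ordering
  and grid traversal, and a reference generated by the forward model at a
  grid point with the same seeds reproduces exactly (objective 0).
  Forward failures at grid points are warned about and excluded from the
  argmin.
* For recovering the wall parameters $(d_w, \kappa_w)$ the informative
  spatial statistic is the distance-to-wall profile at 0.01 m resolution;
  a coarse occupancy grid cannot resolve the few-centimetre wall layer
  whose width identifies $d_w$. With that statistic plus the turning
  histogram, a 3×3 grid search recovers the generating cell in 5 of 5
  repetitions in the test suite.

## Known limitations

* Two-dimensional swimming only; spots float at a fixed height, fish have
  no vertical motion and no retinal acuity structure.
* No occlusion, no perception range limit, no body collisions, no
  preferred inter-individual distance — consistent with the simulated
  cohesive groups having their modal pairwise distance in the 0–0.1 m bin
  while real groups peak at 0.1–0.2 m.
* Speeds are serially independent; there is no speed regulation model.
* The four-point silhouette reduction underestimates solid angles by a
  shape-dependent factor absorbed into the fitted weights; changing the
  body model or the reduction requires refitting $\alpha$ and $\beta$.
* Group-level statistics only for multi-agent analyses (pairwise
  distances, occupancy); per-individual series are meaningful for
  single-agent runs.
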