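---
title: "Modelling goal-directed and conflict-resolution arm movements with active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling goal-directed and conflict-resolution arm movements with active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activereach)
```

## The problem

Most formal theories of motor control describe movements that pursue an
external goal — reach the cup, press the key. But people also produce small
movements with no goal at all: when a seen fake or virtual hand is displaced
from the hidden real hand, the real hand tends to creep toward it, usually
without the person noticing. `activereach` implements a single control model,
grounded in active inference, in which both kinds of movement fall out of one
operation: gradient descent on variational free energy. The same agent, with
the same equations, reaches targets when given one, drifts toward a rubber
hand when shown one, and does a mixture of both when its virtual hand moves
faster than its real one.

The plant is deliberately minimal: one degree of freedom, the elbow rotating
on a table plane. Everything of interest lives in the interplay between two
sensory channels (proprioception and vision) and two kinds of prediction
error (sensory and model-dynamics).

## The generative process (the real arm)

The world state is the joint angle and its velocity, $(\theta, \theta')$,
advanced by explicit Euler integration of

$$\dot\theta = \theta', \qquad
  \dot\theta' = A + \frac{F_E - \phi\,\mathrm{sign}(\theta')\,
  |\theta'|^{\beta}}{m_{arm}},$$

with action $A$ an angular acceleration, external force $F_E = 0$
throughout, and a *sublinear* damping law ($\beta = 0.5$). Sublinear damping
is a deliberate physical choice: it brings the arm to a crisp stop instead
of the long exponential tail of linear (critical) damping. It also behaves
like stiction near zero velocity — at small $|\theta'|$ the damping
acceleration $\propto\sqrt{|\theta'|}$ is comparatively enormous — which
matters for the settling behaviour discussed at the end.

Observations are
$s_p = \theta + \mathcal N(0, \Sigma_p^2)$ and
$s_v = g(\theta_{src}) + \mathcal N(0, \Sigma_v^2 I_2)$ with the forward
kinematics $g(\theta) = (L\sin\theta,\, L\cos\theta)$; $\theta = 0$ points
the forearm along $+y$ (parallel to the midsagittal plane) and positive
angles rotate toward $+x$. Only the figure in which the workspace is drawn
fixes this orientation, so the convention is ours; any smooth injective
choice would do, and this one is frozen for testability. The visual source
angle $\theta_{src}$ is the real hand, a static fake hand, or a virtual arm
integrating $\dot\theta_{VR} = \text{gain}\times\dot\theta$, depending on
the scenario.

## The generative model (the agent)

The agent tracks the arm in generalized coordinates one order higher than
the plant: $\mu = (\mu_\theta, \mu_{\theta'}, \mu_{\theta''})$. The extra
order exists because the internal dynamics predicts *changes in velocity*,
so an acceleration estimate is needed to score that prediction. The internal
dynamics is a damped point attractor,

$$f_1 = \mu_{\theta'}, \qquad
  f_2 = \frac{\tilde K(\mu_{\theta_T} - \mu_\theta)
        - \tilde\phi\,\mu_{\theta'}}{\tilde m},$$

whose fixed point $\mu_{\theta_T}$ is the goal. With the default
$\tilde\phi = 4$, $\tilde K = 1.3$, $\tilde m = 1.5$ the oscillator is
overdamped ($\tilde\phi^2 = 16 > 4\tilde K\tilde m = 7.8$): the expected
trajectory approaches the goal without overshooting. Rest is not a special
mode but a choice of goal: the attractor is re-assigned to the current
estimate, $\mu_{\theta_T} \leftarrow \mu_\theta$, at every step, so the
elastic term contributes exactly zero error while resting. We implement this
as a per-step re-assignment (rather than a one-time set) precisely so that
the model error vanishes identically, not just approximately. A target is
set directly as a desired joint angle; inverting the forward kinematics from
a Cartesian goal is deliberately out of scope.

## Free energy and its gradients

Under the Laplace approximation with Gaussian likelihoods and
Gaussian conditional priors on the generalized orders, the free energy is a
precision-weighted sum of squared prediction errors (additive constants
dropped):

$$F = \tfrac12\Big[
  \frac{\varepsilon_p^2}{\tilde\Sigma_{sp}} +
  \frac{\lVert\varepsilon_v\rVert^2}{\tilde\Sigma_{sv}} +
  \frac{\varepsilon_{m1}^2}{\Sigma_{\mu'}} +
  \frac{\varepsilon_{m2}^2}{\Sigma_{\mu''}}\Big],$$

with $\varepsilon_p = s_p - \mu_\theta$,
$\varepsilon_v = s_v - g(\mu_\theta)$,
$\varepsilon_{m1} = \mu_{\theta'} - f_1 \equiv 0$ and
$\varepsilon_{m2} = \mu_{\theta''} - f_2$. The two Cartesian components of
the visual error share one precision. The $\Sigma$ parameters enter the
quadratic form at first power; treating them as variances to be squared
makes the high-precision visual channel rectify sensory noise through the
curvature of $g$ and destabilizes inference, so the first-power convention
is structural, not cosmetic.

The belief gradients are the analytic derivatives of this form, including
the model-error pathways $\partial f_2/\partial\mu_\theta = -\tilde K/\tilde m$
and $\partial f_2/\partial\mu_{\theta'} = -\tilde\phi/\tilde m$. Whether the
angle gradient should carry the model-error pathway is the kind of detail
that is easy to get subtly wrong, so the package treats a finite-difference
oracle as ground truth: the test suite checks every gradient against central
differences of the implemented $F$ on a thousand random configurations at
relative tolerance $10^{-6}$. (Dropping the pathway is not benign: the
closed loop then overshoots the target by ~0.26 rad and oscillates.)

Action has no representation inside the model, so its gradient is chained
through an assumed sensitivity of sensations to action. Inverting the
internal dynamics at its equilibrium gives the reflex-arc constant
$\partial s_p/\partial A = -\tilde m/\tilde K$; the visual channel chains
the same constant through the forward-map Jacobian at the inferred angle
(the minimal consistent extension — only the proprioceptive case is
derivable from the internal dynamics alone). The two components are kept
separate so each can be gain-weighted and logged:

$$a_p = \frac{\varepsilon_p}{\tilde\Sigma_{sp}}
        \Big(\!-\frac{\tilde m}{\tilde K}\Big), \qquad
  a_v = \frac{\varepsilon_v^{\top} g'(\mu_\theta)}{\tilde\Sigma_{sv}}
        \Big(\!-\frac{\tilde m}{\tilde K}\Big).$$

## The perception–action loop

Each step of length $dt$ applies, in this fixed order: belief update, action
update, world update, new sensory sample (which feeds the next iteration):

$$\mu_\theta \mathrel{+}= dt\,(\mu_{\theta'} - k_\mu \partial_{\mu_\theta}F),
\quad
\mu_{\theta'} \mathrel{+}= dt\,(\mu_{\theta''} - k_{\mu'}
  \partial_{\mu_{\theta'}}F),
\quad
\mu_{\theta''} \mathrel{+}= dt\,(-k_{\mu''}\,\varepsilon_{m2}/\Sigma_{\mu''})
  + \sqrt{dt}\,\sigma_{acc}\,\eta,$$

$$A \mathrel{+}= dt\,(k_{A,p}\,a_p + k_{A,v}\,a_v).$$

Two numerical choices here deserve explanation.

**The sign of the action update.** The components $a_p, a_v$ carry the
reflex-arc constant $-\tilde m/\tilde K$, whose sign encodes the
internal-model inversion ("the larger the standing action, the further the
equilibrium sits below the goal"). The *physical* sensitivity has the
opposite sign: a positive angular acceleration raises the sensed angle.
Descending free energy through the arm that actually exists therefore means
adding $dt\,k_A \cdot a$ rather than subtracting it. This is easy to verify
in simulation: with the subtraction, the arm accelerates away from every
goal and diverges within seconds; with the addition, all the behaviours
below follow. We document the positive form as the package's definition of
the loop.

**The acceleration fluctuation.** The inferred acceleration has no
deterministic drive beyond its (small, $k_{\mu''} = 10^{-3}$) gradient term;
its evolution is modelled as small random fluctuations, entered as the
Euler–Maruyama term above with $\sigma_{acc} = 10^{-3}$ by default. The
magnitude is a modelling choice (nothing pins it); it is configurable, it is
treated as a noise source (so the noise-free fixed-point test sets it to
zero), and the results are insensitive to it over at least two orders of
magnitude.

Action is *integrated* ($\dot A \propto$ the gradient), not set
proportionally each step: a proportional action is an order of magnitude too
weak to move this arm against its damping on the simulated timescale.
Integration is explicit Euler at $dt = 10$ ms with no adaptive stepping;
halving $dt$ changes the arrival time of the reach by well under 5%, and the
settling time quoted below by under 0.2%. A divergence guard aborts with a
classed error if $|\theta|$ or $|\mu_\theta|$ exceeds 10 rad (configurable);
no clipping or filtering is ever applied to $A$.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| $L_{arm}, \tilde L$ | 0.45 | m | forearm length (process and model; unbiased) |
| $m_{arm}, \tilde m$ | 1.5 | kg | forearm mass (unbiased) |
| $\phi, \tilde\phi$ | 4 | — | damping constants (process / internal model) |
| $\beta$ | 0.5 | — | damping–velocity exponent (sublinear stop) |
| $\tilde K$ | 1.3 | — | attractor stiffness; trades off against $k_A$ |
| $\Sigma_p$ | 0.1 | rad | proprioceptive noise SD (≈ 5°) |
| $\Sigma_v$ | 0.01 | m | visual noise SD (1 cm, isotropic) |
| $\tilde\Sigma_{sp}, \tilde\Sigma_{sv}$ | 0.1, 0.01 | rad, m | expected noise (unbiased by default; the rubber-hand scenario lowers visual trust to 0.07) |
| $\Sigma_{\mu'}, \Sigma_{\mu''}$ | 0.01, 0.1 | — | model-dynamics uncertainties |
| $k_\mu$ | (0.1, 0.01, 0.001) | — | perceptual gains per order |
| $k_A$ | (0.3, 0.3) | — | action gains (proprioceptive, visual) |
| $dt$, $t_{sim}$ | 0.01, 20 | s | integration step and horizon |
| $\sigma_{acc}$ | $10^{-3}$ | rad s$^{-2}$ per $\sqrt{s}$ | acceleration fluctuation |

All of these arrive through `process_params()`, `model_params()`, `gains()`
and `loop_config()`; the scenario builders bundle the standard
configurations and expose the knobs that differ between tasks.

## The three scenarios

`scenario_reach()` — visually guided reaching. The agent rests for 3 s,
then the goal $\theta_T = \pi/3$ is disclosed instantaneously (a step, no
ramping). The attractor drags the *expected* dynamics toward the goal,
creating a model-dynamics error; that error pulls the belief ahead of the
arm, which creates sensory errors; and the sensory errors drive the action
that moves the arm. The chain model error → sensory error → action is the
signature of intentional movement.

`scenario_rhi()` — the rubber hand illusion. No goal is ever set. At 3 s
the view of the real hand is replaced by a static fake hand at $\pi/3$
(instantaneous onset; a graded, hierarchically inferred onset is out of
scope). The agent cannot move the fake hand, so $k_{A,v} = 0$, and it
trusts the fake hand less than its own ($\tilde\Sigma_{sv} = 0.07$), which
is also what makes the proprioceptive drift build up gradually rather than
jumping. Vision pulls the belief toward the fake hand; proprioception now
disagrees; the proprioceptive action slowly drives the real hand toward the
fake one. Crucially the model-dynamics error stays at zero throughout — the
agent has no intention — so the velocity estimate, which is informed only
through that error, stays pinned near zero while the arm actually moves.
That is the dissociation the package's metrics quantify: time-mean inferred
velocity two orders of magnitude below the real one.

`scenario_virtual_reach(gain)` — reaching while embodying a virtual arm
with a velocity gain (default 1.3; both arms start co-located). With
gain > 1 the virtual hand arrives at the goal first; the belief, dominated
by the more precise visual channel, settles at the goal while the real hand
is still short of it; and the run ends in a steady state in which the
proprioceptive and visual action components are individually large but
cancel almost exactly (cancellation index ≈ 0.01, where 0 is perfect
cancellation). With gain < 1 the virtual hand lags, so the real hand
overshoots the goal; the steady angle is monotonically decreasing in the
gain. Across gains the real velocity profiles fan out while the inferred
ones nearly coincide — the agent is largely blind to the gain manipulation.
The sub-unity gains shipped in `sweep_velocity_gains()` (0.7, 0.85) are
representative choices, configurable, not facts of the model.

`scenario_control_prop_only()` — either reaching scenario with
$k_A = (0.6, 0)$. Plain reaching still works (proprioception suffices);
under the gained virtual arm, with no visual route to action, nothing stops
the hand at the goal and it follows the virtual hand far beyond it.

## What the generator does and does not emulate

The scenarios *are* the data in this package: there is no external data set,
and the synthetic runs are the study conditions. They emulate — with i.i.d.
Gaussian sensory noise, an instantaneous illusion onset, a perfectly known
body geometry and a single degree of freedom — phenomena that in real
experiments involve graded, hierarchically inferred ownership, correlated
and signal-dependent noise, muscle dynamics, and redundant kinematics.
Passing tests therefore show that the *model* has the claimed dynamics, not
that human arms do; in particular nothing here speaks to conscious
awareness as such, only to the velocity-estimate dissociation that has been
proposed as its computational marker.

## Settling behaviour and known limitations

The default reach is, by design, a slow movement: after disclosure the arm
covers ninety percent of the distance in roughly 3.5–4 s and the movement
is visually over about six to seven seconds into the run. The *strict*
settling time into a ±0.02 rad band (the default of `reach_time()`; the
band and 1-s dwell are this package's conventions, not model quantities) is
much longer, ≈ 18 s noise-free and ≈ 19 s averaged over seeds, and under
sensory noise individual runs can wander at the band's edge indefinitely.
Two ingredients produce this long tail, and both are intrinsic to the
parameterization rather than numerical artifacts (the settling time is
dt-converged to three significant digits):

* the internal attractor is overdamped with slow eigenvalue
  $\lambda = (-\tilde\phi + \sqrt{\tilde\phi^2 - 4\tilde K\tilde m})/(2\tilde m)
  \approx -0.379\,\mathrm{s}^{-1}$, so even the ideal expected trajectory
  needs ≈ 11 s to come within 0.02 rad of the goal;
* the sublinear damping is stiction-like at small velocities, so the final
  approach proceeds as a slow creep in which the integrated action must
  continuously balance a disproportionately large friction.

Users who want an arrival time that matches the visible movement should use
a coarser band (e.g. `tol = 0.1`, giving ≈ 3.6 s after disclosure); users
who want fast strict settling should stiffen the attractor or raise the
action gains, at the cost of leaving the default study conditions.

Other known limitations: a single degree of freedom (so the compensation
null-space of multi-joint setups cannot be represented); no learning of any
internal parameter; no hierarchical inference over whether the seen hand is
one's own; generalized coordinates truncated at the second order.

## Problem sizes used by the tests

The unit and behaviour tests run full 20-s simulations (2001 logged steps)
where the claim concerns the study conditions, shorter 1–6 s runs for
plumbing, 12 seeds for seed-averaged quantities, 1000 random configurations
for the gradient oracle, and a 5-point gain sweep; the whole suite completes
in well under a minute on one core. These sizes are the package's own
choices, large enough that every quoted behaviour is stable across seeds.
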