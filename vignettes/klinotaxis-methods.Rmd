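---
title: "Model and methods: connectome-based klinotaxis with liquid synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: connectome-based klinotaxis with liquid synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
model equations and their assumptions, the parameters that matter and their
defaults, the numerical choices, and what the simulations can and cannot say
about real *C. elegans* behavior.

## The behavioral problem

*C. elegans* locates NaCl sources with two parallel strategies. **Klinotaxis**
is a gradual steering strategy: during the sinusoidal head sweep (one cycle
every 4.2 s) the worm compares concentrations sampled at different phases of
the sweep and biases its turning toward the favorable side. **Random-walk**
locomotion is superimposed on this: even in a uniform environment the turning
rate fluctuates slowly and stochastically, with a roughly normal distribution
(mean 0, SD about 32.3 degrees/mm in behaving worms) and a correlation time
of one guidepost interval (dependence at 6 s, near-independence at 12 s).

The package simulates both behaviors with a single neural circuit: a
30-neuron graded-potential network wired after the worm's connectome, driven
by a two-cell chemosensory model, moving a point agent on a 2D plate, with
all free parameters set by evolutionary optimization rather than by hand.

## Sensory model

Both sensory neurons sense the *temporal* concentration change `dC`: the
per-timestep change scaled into [-1, 1]. The scaling constant defaults to
the largest per-step change achievable at crawling speed in the steepest
part of the environment, so straight radial motion saturates the signal;
this encodes the assumption that the neurons have adapted to the ambient
concentration level and respond only to relative changes.

**ASER** (OFF-cell, graded). A concentration *decrease* sets a stimulus rate
variable to the step size; the rate variable opens a two-state channel pool
(`u` closed, `h` open, `u + h` conserved), and the sensory conductance is
`tanh(gamma_R * h)`, whose saturation reproduces the saturating dependence
of the response peak on the down-step size. The membrane then relaxes toward
the sensory reversal potential through that conductance, on top of ordinary
chemical and electrical afferents.

**ASEL** (ON-cell, stochastic all-or-none). The calcium conductance gate
opens fully (`alpha = 1`) only when the *integrated* signal
`dC + net_L + xi` exceeds a threshold, where `net_L` is the tanh-bounded
afferent input from the rest of the circuit and `xi` is uniform noise
redrawn at every step while the concentration is rising. Because the gate
value after a trigger is always exactly 1, the depolarization amplitude is
invariant to the step size; only the *probability* of triggering grows with
it. The ASEL membrane has no direct synaptic current -- the circuit
influences it only through the trigger pathway -- and its voltage can never
exceed the calcium reversal potential.

The sensory rate constants are not uniquely determined by the behavioral
constraints, so they ship as an editable configuration
(`sensory_params()`): membrane time constants 0.1 s, channel closing rates
0.1/s (the slow-decay scale), trigger-rate decay constants 1 s, conductance
gains 2, trigger threshold 0.5, and noise half-width 0.3. This choice was
calibrated once so that the canonical step-protocol signatures hold -- rare
triggering at a 0.25 up-step, near-certain triggering at a saturating
up-step, identical depolarization peaks, fast rise and slow decay -- and is
deliberately not tuned further. With the default threshold and noise range
the triggering probabilities at up-steps 0.25/0.5/0.75/1.0 are analytically
1/12, 1/2, 11/12, and 1.

## Network and body

Every other neuron follows the standard graded-potential equation: a leak
toward rest, chemical synaptic currents `w_c * f(V_pre + b_pre) * (V - E)`
that drive the voltage toward the edge's reversal potential through the
presynaptic sigmoid output, symmetric ohmic gap junctions, and -- for the
four SMB motor neurons only -- a sinusoidal oscillator input with period
4.2 s, dorsal and ventral cells in antiphase (left/right share phase; only
the dorsoventral antiphase is constrained by the locomotion pattern). The
oscillator stands in for the undulation pattern generator, which the model
does not attempt to produce intrinsically.

The agent is a point at `(x, y)` moving at a constant 0.022 cm/s along its
heading; the turning rate is `w_nmj * (sum of dorsal - sum of ventral motor
outputs)`. Body shape, muscles, and undulatory mechanics are out of scope.

**Connectome.** The packaged edge list
(`inst/extdata/connectome_synthetic.csv`) covers ASEL/ASER, twelve
interneuron pairs (AIY, AIZ, AIB, RIA, RIM, RIV, AVE, AVA, AVB, AVD, PVC,
RIB), and the four SMB motor neurons. It is a *synthetic reconstruction*:
the core pathways (ASE to AIY/AIB, the AIY-AIZ-RIA relay, the command
interneuron block, RIV innervating SMBVL only) follow qualitative circuit
descriptions, and the remaining edges are deterministic padding among
interneurons chosen so that the evolved parameter count is exactly 463 (two
parameters per chemical edge, one per gap junction, one bias per neuron,
plus four globals). The file is ordinary CSV and fully user-replaceable; the
count is recorded in every run manifest. Results that depend on fine wiring
details (for example, which single interneuron ablation is most damaging)
should be read as properties of this scaffold, not of the worm.

## Environments

* conical: constant gradient `kappa` everywhere. The literal
  increasing-with-distance form has its *minimum* at the origin while
  behavior seeks a peak, so the default orientation places the maximum at
  the NaCl placement point (`C = kappa * (r_max - d)`, clipped at 0) and the
  literal form stays available behind `literal = TRUE`. Both have the same
  constant-gradient property that makes this environment the optimization
  arena.
* gaussian: borderless 2D diffusion from a point deposit, with the printed
  `400` denominator factor kept verbatim (any unit mismatch is absorbed into
  the diffusion coefficient). The unprinted constants default to
  `N0 = 0.55`, `D_c = 1e-5` cm^2/s, `d_c = 0.2` cm, `t0 = 3600` s, chosen
  once so that the concentration span across the 4.5 cm start radius matches
  the conical environment's span -- the two environments then exercise the
  same sensory dynamic range, which is the property the generalization test
  needs.
* isotropic: constant field, so `dC = 0`; the arena for random-walk assays.

Runs start 4.5 cm from the peak with a uniform-random heading (seeded), last
800 s for chemotaxis and 1200 s for random-walk assays, and count a run as
"reliable" if the agent ever comes within 0.1 cm of the peak.

## Liquid synapses

Each chemical synapse strength is a stochastic process: independent normal
guideposts `N(w_bar, sigma^2)` drawn every 12 s, linear interpolation in
between, so the strength varies slowly, randomly, and in small increments
around the evolved mean. Negative guideposts are clamped to zero to respect
the non-negativity of chemical strengths; with the small SDs of interest the
clamp is rarely active. Gap junctions, the oscillator coupling and the
neuromuscular gain are not liquid. Setting every SD to zero reproduces the
fixed-weight model bit-for-bit (the interpolation short-circuits on equal
guideposts, and the noise stream discipline is unchanged), which is the
package's strongest internal consistency check.

The half-interval/full-interval lag structure of the interpolated process is
worth stating precisely: two samples 12 s apart share exactly one guidepost
and have a time-averaged correlation of 1/4 (not 0), while samples 6 s apart
correlate near 0.7. The behavioral lag correlations inherit this ordering.

## Optimization

**Stage A (klinotaxis).** All 463 parameters are encoded in [0, 1] and
decoded affinely: strengths to [0, 5], reversal potentials to [-5, 5],
biases to [-5, 5] (deep sigmoid saturation, which the evolved motor neurons
exploit, needs large negative biases), the sensory reversal potentials and
oscillator coupling to [0, 5], the neuromuscular gain to [0, 2] rad/s. The
range width is not cosmetic: the small-signal gain of one synaptic stage is
about `w f' (E - V*) / (1 + sum w f)`, and with strengths and reversal
potentials capped near 2 no pathway through the interneuron layers reaches
unit gain -- a measured three-stage chain attenuates a 0.4-unit sensory
deflection to 0.003 at the motor neuron, far below the steering amplitudes
evolved models must produce. The wider caps admit unit-gain chains while
leaving the operating-point tuning to evolution. Time constants are fixed at
0.1 s and not evolved, matching the published parameter list, which omits
them. Fitness is the mean chemotaxis index
`CI = 1 - (1/T) integral r(t)/r(0) dt` over repeated 800 s trials with
random initial headings; a diverged simulation scores 0. The GA is
steady-state: a mating event picks two random parents (uniform with
replacement, resampled if identical), spawns five candidates evenly along
the open segment between them (fractions k/6 -- the endpoints are the
parents themselves and are excluded), keeps the best candidate, mutates the
whole vector with probability 0.3 by N(0, 0.05^2) noise with clipping, and
replaces the lower-scoring parent if beaten; the full-scale protocol is
population 300, up to 1000 generations, stopping after 50 generations
without a 1e-3 improvement (the improvement tolerance is this package's
reading of "did not improve significantly"). Because the description speaks
of one mating event while also counting generations over a population of
300, this package defines one generation as `events_per_generation` events
(default half the population). Elitist replacement makes the best fitness
non-decreasing by construction, which the test suite asserts.

Two evaluation details matter more than any GA hyperparameter. First,
initial headings: with a handful of *random* headings per evaluation, the
mean CI of a non-sensing agent has a standard deviation of a few tenths, so
a small search reliably "evolves" open-loop paths that exploit heading luck
and collapse on fresh seeds. `ga_config(heading_mode = "even")` (the
default) starts the trials at evenly spaced orientations instead: any
open-loop strategy then averages out over the rotation and only genuine
gradient steering scores above the circling baseline. Second, seeds:
`common_eval_seeds = TRUE` evaluates every genome on one fixed seed set
(common random numbers), so small fitness differences reflect the genomes
rather than trial noise. The scaled-down pipeline in `scripts/acceptance.R`
uses both.

**Stage B (random walk).** With the stage-A genome frozen, the per-edge SDs
are fit so that the turning-rate distribution in an isotropic arena matches
the reference normal (mean 0, SD 32.3 degrees/mm). The similarity score is
`-(|mu|/32.3 + |sigma - 32.3|/32.3)` plus the mean one-sample K-S P value as
a normality bonus; it is maximal exactly at the target. To keep the search
desk-scale the SD vector is a single global scale (optionally times per-edge
multipliers in [0.5, 1.5]); the full per-edge search is supported but not
the default.

## Numerical choices

* Fixed `dt = 0.01` s throughout. The network neurons use a semi-implicit
  Euler update: given the presynaptic outputs, the voltage equation is
  linear in `V`, so the leak and conductance terms are treated implicitly
  (`V' = (V + a drive) / (1 + a (1 + sum w f + sum w_g))` with
  `a = dt/tau`). This is unconditionally stable for any parameter draw --
  essential because random genomes under the decode ranges above routinely
  exceed the explicit-Euler stability bound, which would kill the entire
  initial GA population -- and has the same fixed points and first-order
  accuracy as the explicit form. The sensory neurons, whose total
  conductance is bounded by construction, use the plain explicit update,
  and the channel-state pair advances by a single shared increment so
  `u + h` is conserved to machine precision. The test suite checks that
  halving `dt` moves an 800 s trajectory endpoint by less than 1% of the
  path length and a sensory peak by less than 1%.
* Extreme corners (maximal excitation onto the explicitly integrated
  sensory membrane) can still diverge; divergence is detected, the
  trajectory truncated with a warning, and the trial scored CI = 0 -- the
  GA treats such genomes as dead ends rather than crashing.
* The plain-R sensory steppers and the compiled simulator implement the same
  update order (voltage derivative with the pre-update conductance, then the
  stimulus rate variable, then the channel states, then the conductance);
  a test pins the two routes together at 1e-12, and an adaptive
  high-accuracy integration (deSolve) serves as the independent oracle for
  the response-shape properties.
* The chemotaxis index is accumulated by trapezoidal quadrature at full `dt`
  resolution inside the simulator, independent of the trajectory recording
  stride.
* Turning statistics are computed per locomotion cycle (4.2 s); 6 s and 12 s
  lags are realized by linear interpolation between cycles. Turning rate is
  turning bias (degrees per cycle) divided by the translational distance of
  that cycle in mm. Relationship curves use 13 bearing bins over (-180, 180]
  and 11 gradient bins over [-1, 1] (odd counts center a zero bin); empty
  bins are reported as missing, never as zero.

## What the scaled-down pipeline shows -- and what it does not

`scripts/acceptance.R` runs the pipeline at desk scale in two tiers. Tier A
evolves from scratch with a reduced stage-A GA (population 24, 25
generations, 4 trials x 800 s per evaluation, common seeds, even headings)
and reports that search's own best fitness and fresh-seed chemotaxis score.
Tier B loads the packaged example genome -- evolved with the same
`run_ga()` machinery over several warm-started legs totalling roughly
2.5 x 10^4 fitness evaluations (its evolution seeds and scores are stored
in the JSON) -- and runs the standard scoring protocols on it: 20-trial
chemotaxis in the conical and gaussian environments, a reduced stage-B SD
fit, 30 x 1200 s random-walk tracks, and an ASE-pair ablation control.
These problem sizes are the package's chosen desk-scale defaults; the
full-scale protocol (population 300, up to 1000 generations, 50- and
500-run scoring batteries) is available through `ga_config()` and the CLI
but takes days on one CPU.

Reduced searches find weaker models than a full-size run: the packaged
genome climbs the gradient from most initial headings (mean CI around 0.4
in the conical field at 800 s, reliability around 0.1) but does not reach
the published ensemble's `fitness > 0.7, reliability > 0.5` success tier,
and it climbs mainly by modulating the magnitude of its curvature with
bearing rather than by the fully antisymmetric sinusoidal steering that
large-budget searches produce. Single-model statistics carry no ensemble
error bars. What the pipeline does establish is mechanistic: the evolved
model climbs gradients in both environments without re-tuning, liquid
synapses alone generate turning-rate fluctuations with the interpolation
process's 6 s/12 s correlation signature, the SD fit recovers the
behavioral SD target closely, and ablating the ASE pair abolishes gradient
climbing entirely.

One divergence from the large-budget picture is worth flagging: robust
models keep most of their chemotaxis performance when the fitted liquid
noise is switched on, whereas the packaged desk-scale model loses its
(weaker) klinotaxis under the same noise level -- its steering relies on
finer weight tuning than a fully evolved model's, so weight fluctuations
with an SD matched to the behavioral random walk overwhelm it. The
pipeline reports that number as computed rather than hiding the fragility.

The synthetic-data side has the same character: the generator *is* the
simulator, so tests demonstrate internal consistency of model, statistics,
and optimization -- not that the real worm's circuit behaves this way. The
connectome scaffold is qualitative, body mechanics are absent, and the
sharp-turn (pirouette) machinery is a user-supplied hook precisely because
the fitted probability equation from the behavioral literature is not
bundled.

## Known limitations

* The sensory constants live in configuration, not in data; different
  choices that satisfy the same qualitative constraints would give
  quantitatively different steering gains.
* Stage-B's default single-scale SD search cannot reshape the *relative*
  noise across synapses, only its overall level.
* The random-connectome control preserves edge totals but not degree
  sequences, matching its stated contract; it is a null model for "wiring
  specificity", not for "degree structure".
* Evolution and scoring use the same simulator; there is no held-out
  physical validation inside the package.
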