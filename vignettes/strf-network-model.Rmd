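---
title: "Modeling task-related STRF plasticity with a spiking cortical network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling task-related STRF plasticity with a spiking cortical network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strfnet)
```

## The scientific problem

Neurons in primary auditory cortex (A1) are characterized by their
spectrotemporal receptive field (STRF): a lag-by-frequency kernel
describing how firing rate follows stimulus spectral energy. When an
animal engages in a tone-detection task, A1 STRFs change within seconds —
excitatory and inhibitory subfields grow, shrink, or move. The mechanism
of this rapid task-related plasticity is unknown, because an STRF is a
functional readout of an entire network, not of any one synapse.

`strfnet` implements a complete in-silico version of the experimental
pipeline so the question can be inverted: given a target STRF (recorded,
or synthesized from a known ground-truth network), which synaptic
parameters of a small tonotopic spiking network must change to reproduce
it? The pipeline is:

1. **Stimuli** — temporally orthogonal ripple combinations (TORCs):
   broadband stimuli whose spectral envelope is the superposition of six
   drifting sinusoidal ripples. Because the ripples in each TORC have
   pairwise distinct velocities, the ensemble's spectrotemporal
   autocorrelation is concentrated at zero lag and zero channel
   difference, which makes plain reverse correlation an (approximately)
   unbiased STRF estimator.
2. **Periphery** — 15 auditory-nerve channels with center frequencies
   log-spaced from 0.5 to 16 kHz. Each channel converts the stimulus
   envelope at its frequency into an instantaneous driving rate and then
   into stochastic discharge times via an inhomogeneous Poisson generator.
3. **Cortex** — 15 leaky integrate-and-fire neurons, one per channel
   (peripheral channel *c* drives neuron *c* only), all 225 pairwise
   cortico-cortical synapses present as parameters. Synapses have
   alpha-function conductance time courses.
4. **STRF estimation** — reverse correlation of one neuron's spikes
   against the stimulus dynamic spectra, with per-channel stimulus-power
   normalization.
5. **Fitting** — an elitist genetic algorithm (GA) over the 255 integer
   codes (225 weights, 15 input strengths, 15 input delays) minimizing a
   significance-weighted cost between the model STRF and the target.
6. **Interpretation** — perturbation sensitivity analysis of the fitted
   genome, averaged over independent GA repeats, and a two-state
   (passive vs. behavioral) comparison diagram.

## The neuron and synapse model

The membrane obeys

$$\tau_m \frac{dv}{dt} = (v_{rest} - v) + R_m\, g_{syn}(t)\,(v_{rev} - v)
  + v_{tonic},$$

a conductance-based formulation: synaptic drive enters through a
conductance times the driving force $(v_{rev} - v)$, with
$v_{rev} = -30$ mV for excitatory and $-90$ mV for inhibitory synapses,
so positive synaptic codes always depolarize and negative codes always
hyperpolarize. Each synaptic event contributes an alpha conductance
$g(t) = A\,(t/\tau_s)\,e^{-t/\tau_s}$ peaking $\tau_s$ after the event at
$A/e$.

| parameter | value | meaning |
|---|---|---|
| $\tau_m$ | 10 ms | membrane time constant |
| $v_{rest}$ | −70 mV | resting potential |
| $R_m$ | 4 MΩ | membrane resistance |
| $v_E$, $v_I$ | −30, −90 mV | synaptic reversal potentials |
| $v_K$ | −90 mV | reset / after-hyperpolarization potential |
| $g_m$ | 2 µS | maximum synaptic conductance (at code ±5) |
| $\tau_s$ | 2 ms | synaptic time constant |
| $dt$ | 0.25 ms | integration step |
| $v_{th}$ | −50 mV | spike threshold (package default) |
| refractory | 1 ms | absolute refractory period (package default) |

Threshold, reset target and refractory period are declared modeling
defaults of this package: the conductance-based membrane with the listed
reversal potentials does not by itself fix them, and no attempt is made to
present them as measured values. Resetting to $v_K = -90$ mV implements
the after-hyperpolarization that, together with the TORC envelope
statistics, produces the faint alternating side-lobes visible in clean
simulated STRFs.

**Integer synaptic codes.** Every synapse is coded by an integer in
−5..5; the code scales the maximum conductance as $A = g_m |code|/5$, so
the extreme codes reach $g_m$ and *single* synaptic events are
subthreshold — cortical spikes require temporal summation of several
peripheral events, which is what makes the input *strength* codes
behaviorally meaningful gain parameters rather than binary switches.
Input delay codes map linearly to a 0–50 ms cochlea-to-cortex
transmission delay (`25 + 5*code` ms). Cortico-cortical transmission
delays are not free parameters: they grow with tonotopic separation
(2 ms + 3 ms/octave of CF distance, configurable), reflecting
distance-proportional intracortical conduction, and they are what delays
lateral STRF subfields relative to the primary one.

**Tonic drive.** Fitting contexts give every neuron a constant
depolarizing drive calibrated in closed form ([tonicForRate()]) to fire
at 10 Hz in silence; networks with tonic firing respond more robustly and
let inhibitory inputs leave a visible (negative) STRF footprint,
since suppression of a silent neuron is unobservable.

## Stimulus synthesis choices

A TORC's envelope is $S(t,x) = \sum_i a_i \cos(2\pi(\omega_i t +
\epsilon_i x) + \phi_i)$ on an octave axis $x$. Defaults: six ripples per
TORC; per-TORC velocity family $\omega = k\,\Delta\omega$, $k = 1..6$
with $\Delta\omega \in \{4, 8\}$ Hz alternating across the set (sets
spanning 4–24 Hz and 8–48 Hz) and alternating drift signs within a TORC;
densities uniform in 0–1.4 cycles/octave; phases uniform; unit
amplitudes. The absolute envelope scale is arbitrary — reverse
correlation and the fit cost operate on quantities estimated with the
same pipeline on both sides — so no loudness calibration is attempted.
The envelope is sampled at 2 ms (250 Hz, comfortably above twice the
fastest 48 Hz ripple). Audio rendering (20 carriers/octave, random fixed
phases, modulation depth 0.9, 48 kHz) exists for listening and for
driving the gammatone audio path; the numerical pipeline works directly
on the envelopes.

## The periphery stands in for the auditory nerve

The full biophysical auditory-nerve chain is deliberately not
reproduced. For STRF estimation the operative property of the periphery
is band-pass channelization plus stochastic discharge generation, so the
front end is: envelope of the stimulus at each channel's center frequency
(or, for raw audio, a 4th-order gammatone filter, half-wave
rectification, 250 Hz low-pass and square-root compression), an affine
map to a rate, $\lambda = r_{spont} + r_{gain}\,\max(0, S)$ clipped to
$[0, r_{max}]$ with defaults 20, 150 and 400 events/s, and Poisson
thinning with a 0.75 ms dead time. Any alternative periphery that
produces a `DischargeTrain` on the same `ChannelBank` (e.g. an external
biophysical model) plugs into the cortical stage unchanged — this adapter
contract is part of the tested API.

## STRF estimation and the fit cost

Reverse correlation averages the stimulus envelope preceding each spike:
$C(\tau, x) = (1/T)\sum_{spikes} S(t_{sp} - \tau, x)$, accumulated over
all stimuli and repetitions, then divided per channel by the ensemble's
mean envelope power. This per-channel normalization implements the
"ensemble autocorrelation ≈ delta" reduction; the full autocorrelation
kernel is available ([phiKernel()]) for checking how good that
approximation is for a given stimulus set. The default lag window is
0–250 ms in 2 ms steps (the estimator's own choice; reduced-scale test
contexts use 120 ms, which covers the largest codable delay plus the
synaptic/membrane response).

Significance masking is two-sided: a point is significant if it is at
least 3 standard deviations from the mean of the whole STRF. The
two-sided form is deliberate — inhibitory subfields are as real as
excitatory ones and must be able to anchor the fit. A constant STRF
(zero standard deviation) has an empty mask. The fit cost is
$\sum |M - E| \cdot sig(E)$ with weight 1 on the target's significant
points and 0.1 elsewhere.

**Scale handling.** By default the cost compares the two STRFs on their
native scale. Model and target are always estimated by the identical
reverse-correlation pipeline from the identical stimulus ensemble here,
so their units are commensurate, and a native-scale comparison keeps the
cost sensitive to pure gain changes — without this, a one-step change of
the only input-strength code is nearly invisible to the cost and the
sensitivity analysis systematically misses input-strength parameters,
which defeats the point of the two-state comparison. For targets on an
incommensurate amplitude scale, `strfCost(..., normalize = TRUE)`
compares unit-peak-normalized shapes instead.

## Fitting and interpretation

The GA is deliberately plain: population 1000, the best 40 pass
unchanged (elitism, which makes the best-cost history provably
non-increasing), the best 100 serve as parents, 480 offspring from
uniform per-gene crossover of random parent pairs and 480 from per-gene
mutation (resampling probability 0.05, uniform within bounds). Crossover
and mutation operator details and the mutation rate are package choices;
nothing in the procedure depends delicately on them. One crucial
determinism decision: the peripheral discharge seeds are fixed once per
evaluation context, so every genome is scored against identical
stochastic input. Without this the cost landscape is noisy,
re-evaluation of an elite genome would change its cost, and elitism would
be meaningless.

Sensitivity analysis perturbs each fitted parameter by ±1 code step and
records the mean absolute cost change (boundary codes use the single
feasible perturbation); scores are normalized to sum to one. Because the
255-dimensional fit is degenerate — independent GA runs find different
genomes with similar costs — profiles are averaged over five independent
fit repeats before the top-2 parameters per state are declared
"important". The two-state diagram then contains the union of both
states' top-2 parameters plus context parameters that trace the signal
path (cochlear input to every implicated neuron, synapses from implicated
neurons to the recorded neuron, and the recorded neuron's own input),
each annotated with the mean ± sd of its integer value across repeats.

## Numerical implementation

Integration is exponential Euler per 0.25 ms step; with no synaptic input
this is exact for the leak equation, which the tests exploit by checking
the closed-form relaxation to 0.1%. Alpha conductances use the standard
two-state recursion (exact for sums of alpha kernels), so synaptic
time courses carry no discretization error; an impulse lands in the
auxiliary state at its arrival step and the conductance is zero at the
event time itself. Delayed events are deposited in per-step impulse
buffers (an event queue); spikes reset the membrane and clamp it for the
refractory period. Halving $dt$ changes spike counts of a reference
simulation by under 5% (tested). Sorting in the GA is stable by
(cost, insertion index); top-k extraction in the sensitivity analysis
breaks ties toward the lower parameter index. All randomness flows from
user-supplied integer seeds through a positional splitting rule
(`deriveSeeds`); reruns with the same master seed are bit-identical.

## What the synthetic ground truth does and does not show

The package ships scenario generators (single excitatory or inhibitory
input at a chosen CF, delayed input, lateral excitation/inhibition
between two driven neurons) whose STRFs have known qualitative
signatures, and uses them as fitting targets in place of in-vivo
recordings, which cannot be distributed with the package. Passing the
recovery suite shows that the estimator, the optimizer and the
sensitivity analysis are internally consistent: parameters that generated
a target are re-identified from its STRF alone. It does not show that
real A1 STRF changes are caused by the recovered parameters — real
recordings have non-Poisson spiking, adaptation, correlated noise across
repetitions, and STRF structure (e.g. broad, slow subfields) that the
noise-free LIF pipeline does not produce. The reduced 5-neuron
configuration used in the test suite (10 one-second TORCs, one
repetition, population 60, 15 generations) is a desk-scale setting chosen
so the full recovery experiments run in minutes; the full-scale
configuration (15 neurons, 30 TORCs × 4 repetitions, population 1000,
100 generations) is supported and selected by the defaults of
`gaConfig()` and `makeEvalContext()`.

## Known limitations

* The periphery is phenomenological; synaptic adaptation, two-tone
  suppression and level dependence are absent by design.
* Reverse correlation is band-limited by the stimulus: structure faster
  than the fastest ripple velocity (48 Hz) or finer than the ripple
  density range (1.4 cycles/octave) is not probed, so sharp kernels are
  recovered smoothed.
* The cost treats STRF points independently; there is no smoothness prior.
* Sensitivity is local (±1 code); it ranks parameters around a solution
  and is not a global variance decomposition.

## A minimal session

```{r example, eval = FALSE}
bank <- cfGrid()                                   # 15 channels, 0.5-16 kHz
torcs <- makeTorcSet(30, seed = 1)
ctx <- makeEvalContext(bank, torcs, seed = 11, reps = 4)

sc <- makeScenario("lateral_inhib")                # known ground truth
target <- makeTarget(sc, ctx)
plotStrf(target)

fit <- runGA(target, gaConfigReduced(), ctx, seed = 5)
prof <- sensitivityProfile(fit$bestGenome, target, ctx)
importantParams(prof, 2)
```
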