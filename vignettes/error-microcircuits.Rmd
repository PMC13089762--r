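---
title: "Error-neuron microcircuits: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-neuron microcircuits: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`errnet` simulates networks of cortical areas in which each area holds two
pyramidal-cell populations: **representation units**, whose prospective
somatic rate carries the network's predictions, and **error units**, whose
soma multiplicatively combines errors projected from other areas with the
local activation-function derivative. Unlike classical predictive-coding
networks, errors are not computed as local differences in every area; they
are computed once, at the target area, and *projected* between error
populations — the network is a dynamical, always-on implementation of the
backpropagation error recursion.

## Representation units

Each representation soma leak-integrates two dendritic compartments,

$$C_m \dot u^{\mathrm{som}} = -g_l u^{\mathrm{som}}
  - g^{\mathrm{rep}} (u^{\mathrm{som}} - u^{\mathrm{pred}})
  - g^{\mathrm{err}} (u^{\mathrm{som}} - u^{\mathrm{err}}),$$

where the prediction compartment sums rates from all other areas through
the forward weights, $u^{\mathrm{pred}}_\ell = \sum_{k\neq\ell} W_{\ell,k}
r^r_k$, and the error compartment reads the local error population through
the static coupling $u^{\mathrm{err}}_\ell = L^{RE}_\ell r^E_\ell$. The
output is the **prospective rate**

$$r^r = \phi(\breve u) = \phi(u + \tau_r \dot u),$$

so with $\tau_r = \tau_m \equiv C_m / (g_l + g^{\mathrm{rep}} +
g^{\mathrm{err}})$ the rate tracks the instantaneous dendritic drive even
though the membrane is slow ("quasi-instantaneous" preset), while
$\tau_r < \tau_m$ leaves a controlled lag whose leaky integration serves
as short-term memory (retrospective preset, $\tau_r = 0$).

## Error units

Error somata integrate the *product* of a representation-receiving
dendritic factor and an error-receiving compartment,

$$C_m \dot e^{\mathrm{som}} = -g_l e^{\mathrm{som}}
  - g^{\mathrm{den}}\bigl(e^{\mathrm{som}} -
  [L^{ER}\phi'(\breve u^{\mathrm{som}})] \odot \textstyle\sum_m B_{\ell,m}
  r^E_m\bigr),$$

with the output area instead gating the mismatch against a target rate,
$[L^{ER}\phi'] \odot (r^{\mathrm{tgt}} - r^r_N)$, through $g^{\mathrm{nudge}}$.
Error units are linear and quasi-instantaneous
($\tau_r^E = \tau_m^E$), so their prospective voltage tracks the dendritic
drive tick by tick; at equilibrium the prospective error voltages satisfy
the closed-form recursion implemented in `steady_state_errors()`, which the
test-suite uses as the oracle for simulated equilibria.

## Plasticity

Forward weights follow an always-on delta rule whose postsynaptic factor is
the mismatch between the prospective somatic voltage and the dendritic
prediction,

$$\dot W \propto \bigl[\breve u^{\mathrm{som}} -
  \tfrac{g^{\mathrm{rep}}}{g^{\mathrm{tot}}} u^{\mathrm{pred}}\bigr]\,
  (r^{\mathrm{pre}})^{\!\top}.$$

For $\tau_r = \tau_m$ this is *algebraically identical* (asserted to 1e-12
in the tests) to the error-compartment form $\tfrac{g^{\mathrm{err}}}
{g^{\mathrm{tot}}} u^{\mathrm{err}} (r^{\mathrm{pre}})^{\!\top}$. For
retrospective units the two forms differ: the voltage-mismatch form then
contains a lag-transient term — whenever the input switches, $u$ trails
$\tfrac{g^{\mathrm{rep}}}{g^{\mathrm{tot}}}u^{\mathrm{pred}}$ and the rule
integrates a systematic decrement that acts as strong weight decay over an
800–1000-tick memory trial, erasing learned structure within an epoch at
any usable learning rate (the decay-to-error ratio is independent of the
learning rate, so no tuning escapes it). Quasi-instantaneous error units
compensate exactly this membrane lag, which is why the memory-task recipe
(`dms_network()`) uses the error-compartment form; both are available via
`mc_network(..., plasticity_rule = )` and coincide in every
quasi-instantaneous configuration.

Error-projecting weights approximate phaseless alignment learning by a
transpose-plus-frozen-noise refresh after every tick:
$B_{\ell,m} = [\mathbf{1}^{ER} W_{m,\ell} \mathbf{1}^{RE}]^\top +
\Xi_{\ell,m}$, with $\Xi \sim \mathcal U(-0.5, 0.5)$ sampled once at
initialisation. The padded identities handle unequal population counts
($n_R \neq n_E$); local couplings $L^{RE}, L^{ER}$ are noisy padded
identities ($\mathcal U(-\sigma_L, \sigma_L)$) and static. Full dynamical
learning of $B$ from temporal noise is out of scope.

## Backpropagation as a limit

With a strict hierarchy, identity local coupling, noiseless transport and
$g^{\mathrm{err}} \to 0$, a settled network computes the forward pass
$r_\ell = \phi(\lambda W_\ell r_{\ell-1})$ of a layered network with input
gain $\lambda = g^{\mathrm{rep}} / g^{\mathrm{tot}}$, and the first
post-settling weight update is parallel (per layer) to that network's
backpropagation gradient. `as_ann()` constructs this equivalent reference
explicitly — including $\lambda$, which is what makes the per-layer cosine
comparison exact rather than approximate — and `ideal_bp_network()` is the
corresponding preset. Because nudging contaminates every soma at finite
$g^{\mathrm{err}}$ (there is no buffered "fixed prediction"), alignment
degrades gracefully as $g^{\mathrm{err}}$ grows; learning still works at
the reference value $g^{\mathrm{err}} = 0.06$.

# Numerical scheme

One tick applies, in order: (1) all dendritic drives from the *previous*
tick's rates and derivatives (synchronous across areas, hence
seed-reproducible and order-independent; signals propagate one area per
tick); (2) a forward-Euler step of every somatic voltage; (3) prospective
voltages, rates and $\phi'$; (4) plasticity and the feedback refresh. The
derivative stored for the prospective voltage is the analytic right-hand
side evaluated at the *updated* voltage — this, not a finite difference of
stored voltages, keeps $\breve u = (g^{\mathrm{rep}} u^{\mathrm{pred}} +
g^{\mathrm{err}} u^{\mathrm{err}})/g^{\mathrm{tot}}$ an exact identity at
$\tau_r = \tau_m$ and avoids amplifying $O(\mathrm{d}t)$ noise.

Each presented sample begins with a settling phase (default 10 ticks,
configurable) during which plasticity is frozen; always-active targets
remain applied during settling, while delayed targets (the memory task)
stay off until their window. Network state persists across samples and
epochs — the simulation is phaseless and continuous; evaluation runs
(`mc_predict()`) instead start from rest, with targets off and plasticity
off. Non-finite voltages abort with the tick and area identified. Areas
with $n_E = 0$ are legal: their error population is simply absent and
$u^{\mathrm{err}} \equiv 0$.

The per-tick dynamics are implemented twice: a pure-R reference
(`mc_tick()`), which is the readable specification and drives closed-loop
control, and a compiled core used for training; a test asserts their
agreement to 1e-12 over random networks, weights included.

# Parameters

| symbol | meaning | default | notes |
|---|---|---|---|
| $C_m$ | capacitance | 1 | conductances then have units 1/time |
| $g_l$ | somatic leak | 0.03 | 0.3 in the memory task (shorter $\tau_m \approx 2.2$) |
| $g^{\mathrm{rep}}$ | prediction coupling | 0.1 | |
| $g^{\mathrm{err}}$ | error nudging | 0.06 | 6e-4 for cart pole (slow learning); 1e-4 in the ideal-backprop preset |
| $g^{\mathrm{den}}$ | error-dendrite coupling | 0.1 | |
| $g^{\mathrm{nudge}}$ | output nudging | 0.06 | |
| $\tau_r^r$ | prospective constant | $\tau_m^r$ | 0 (retrospective) for memory |
| $\mathrm{d}t$ | tick | 0.01 | time units |
| $T_{\mathrm{pres}}$ | presentation | 0.2 | 1 for cart pole; trial-length for memory |
| $\sigma_L$ | local-coupling noise | 0.3 | 0.03 generative (dense local fan-in), 0.1 Yin-Yang |
| $B$ noise | transport noise | $\mathcal U(\pm 0.5)$ | $\pm 0.1$ Yin-Yang, 0 ideal preset |
| $\eta$ | learning rate | per task | the one tuned group; recorded in `inst/extdata/configs/` and the recipe defaults |

Time units deserve a remark: the printed parameter tables are mutually
inconsistent if one fixes a single unit (a leak of 0.3 gives $\tau_m
\approx 2.2$ units, advertised as $\approx 220$ ms, with $\mathrm{d}t =
10^{-2}$ units). The package therefore treats the time unit as
configuration. For the memory task the coherent reading sets 1 unit =
100 ms, i.e. 1 ms ticks, 250-tick stimulus phases, trials of 800–1000
ticks and $\tau_m \approx 217$ ticks; `generate_dms()` implements exactly
that.

Learning rates are the one deliberately free group (no values are printed
for them; the update rule has unit gain). Defaults per task were tuned
once for stable convergence and live in the recipe functions
(`ts_network()`, `dms_network()`, `cartpole_network()`,
`generative_network()`, `yinyang_network()`) and the shipped YAML presets.

# Task generators: what they emulate, and what they do not

All generators are pure functions of their parameters and the R
random-number state.

* **Cart pole / LQR teacher** (`cartpole_step()`, `lqr_gain()`,
  `lqr_teacher_dataset()`): a standard frictionless cart-pole plant (cart
  mass 1, pole mass 0.1, half-length 0.5, gravity 9.8, Euler step 0.02 s,
  one controller tick per plant step), a continuous linearisation solved
  by discrete Riccati value iteration, and 500 state-force pairs with
  states $\sim \mathcal U(-1.5, 1.5)^4$. Because the readout is a bounded
  rate, targets are scaled by a force gain ($1.5\sum_i |K_i|$, so every
  achievable force maps inside the activation range) and the controller
  output is scaled back in the closed loop. The plant's parameters and the
  cost matrices ($Q = \mathrm{diag}(1,1,10,1)$, $R = 5$) are configuration,
  chosen so the teacher stabilises the nonlinear plant from tilts up to
  $\sim 57°$. No sensor noise, friction or delay is modelled.
* **Delayed match-to-sample** (`generate_dms()`): 1-D time series of
  fixation (250 ticks), stimulus $\pm 1$ (250), delay $\mathcal U(50,250)$,
  stimulus (250); target $= \pm$`target_amplitude` encoding the XNOR of
  the stimulus signs, applied during the final stimulus stage. Under the
  synchronous update an error born on a literal single final tick can
  never cross two areas, so "target at the last step" is read as the last
  *stage*; `target_window = "final"` retains the literal reading. The
  target amplitude (default 5, a quarter of the $20\tanh(x-0.5)$ readout
  range) sets the free-running decision margin; unit targets leave the
  margin at 0.05 voltage and the readout hovers at the threshold.
  Conditions are balanced 13/13/12/12 at $n = 50$.
* **Yin-Yang** (`generate_yinyang()`): outer radius $r$ at (0.5, 0.5),
  half-circles $r/2$, dots $r/4$; uniform sampling with probabilistic
  class balancing (the standard benchmark construction, expected one third
  per class), mirrored encoding $(x, y, 1-x, 1-y)$.
* **Teacher-student** (`generate_teacher_student()`): a fixed random
  teacher of the same architecture as the student, widths halving towards
  the scalar output so that every area must train; inputs
  $\mathcal U(0,1)$; 100/100/100 splits; teachers resampled until the
  target variance on the training inputs is at least 1e-3 (the
  operationalisation of "non-trivial"). Note the task *instance* is the
  teacher draw: the achievable test-loss floor varies substantially
  between teachers, which matters when comparing to any single reported
  number.
* **Generative images** (`generate_image_task()`): ten deterministic
  (one-hot class, image) pairs; train, validation and test sets coincide
  by construction. The default source renders synthetic procedural
  patterns (oriented gratings / centred rings) at a configurable side
  length — 28 for the full-scale protocol, 8 for the reduced protocols —
  and a flat-CSV loader (label + pixels) accepts user-supplied exemplars.
  The synthetic patterns are labelled as such throughout; they emulate
  only the *structure* of the protocol (a deterministic class-conditioned
  pixel target in $[0,1]$), not natural image statistics.

Consequently, passing tests show that the *mechanisms* behave as derived —
gradient recovery, error transport, memory via slow membranes, recovery
through skip connections, sensitivity to error-side variability — under
clean, low-dimensional, noiseless-input conditions. They do not show
robustness to natural images, sensor noise, or trial-to-trial input
variability.

# Dendritic derivative reconstruction

`reconstruct_phi_prime()` demonstrates how an error-unit dendrite can
estimate $\phi'(u)$ locally: white noise $\xi \sim \mathcal N(0,
\sigma_\xi)$ rides on the presynaptic voltage, the rate $\phi(u + \xi)
\approx \phi(u) + \xi \phi'(u)$ is high-pass filtered (first-order,
$\tau_\xi = 10$ ticks) to isolate the noise-borne term, rectified, and
averaged over the presentation window. For Gaussian noise of post-filter
standard deviation $s$, $E[\mathrm{relu}(\xi\phi')] = s\,\phi'/\sqrt{2\pi}$
for $\phi' \ge 0$ — the documented proportionality constant, so absolute
comparisons are possible, not only correlations. A burn-in of $2\tau_\xi$
ticks is discarded while the filter accumulator settles; without it the
start-up transient biases short windows. The estimate assumes
$|u| \gg |\xi|$ (default $\sigma_\xi = 0.05$), smooth monotone $\phi$, and
$T_{\mathrm{pres}} \gg \tau_\xi$ (a warning is emitted otherwise);
non-monotone activations with $\phi' < 0$ are out of scope, as rectified
rates cannot encode a sign. The main simulator uses the analytic $\phi'$;
reconstruction is the opt-in demonstration (`phi_prime_profile()`, CLI
subcommand `phi-demo`).

# Design choices where the design was open

* **Variability composition**: per-neuron slopes $a_i \sim \mathcal
  N(1, \sigma_{\mathrm{act}})$ and offsets $b_i \sim \mathcal N(0,
  \sigma_{\mathrm{act}})$ compose as $\phi(a_i u + b_i)$ (both inside the
  nonlinearity). With linear error units the error rate becomes
  $a_i e + b_i$, so offsets can flip error signs — the mechanism behind
  the error-side fragility the variability protocol exhibits.
* **Loss**: summed squared error over output units, averaged over samples.
* **Input clamping**: input-area rates are set to the stimulus, not
  nudged.
* **Ablation**: zeroes the forward block, freezes its learning rate, and
  clears the mirrored feedback block's frozen noise (an approximate-PAL
  feedback projection decays once its forward partner is gone); ablating
  an already-ablated block is a no-op, naming a non-existent block an
  error.
* **Inter-area densities**: the measured connectome behind the loose
  hierarchy is not printed anywhere reproducible, so the density matrix
  is user input (CSV; `read_density_csv()`), with a documented default —
  log-spaced decay with hierarchical distance, zero diagonal, entries
  below $10^{-2}$ rounded to zero, initial weight scale proportional to
  relative density. Forward blocks follow the flow direction; feedback
  blocks mirror them.
* **Frozen transport noise**: $\Xi$ is sampled once at initialisation and
  added to a changing $W^\top$ on every refresh (the "sampled once"
  reading), rather than resampled per tick.
* **Aggregation over seeds**: protocol-level checks aggregate as medians
  over seeds, matching how such results are usually plotted; this matters
  for occasional diverging initialisations of the generative baseline.
* **Cart-pole local noise**: a half-width of 3 on the scalar output-area
  couplings flips the sign of the local error loop in $4/9$ of draws;
  flipped draws anti-learn and the controller falls for the whole episode.
  No seed-aggregation can reconcile that with a controller reported on par
  with its teacher, and every other protocol uses $\sigma_L \in \{0.3,
  0.1, 0.03\}$, so the realistic cart-pole recipe uses $\sigma_L = 0.3$;
  larger values remain constructible through `mc_network()`.

# Problem sizes

The shipped test-suite and acceptance script run the protocols at sizes
chosen as this package's study conditions: teacher-student complexities
1–3 at 600 epochs (5 seeds; the 10-fold loss reduction is typically
reached before epoch 300), the frozen-control at its full 1000 epochs and
10 seeds, the memory task at full temporal resolution (800–1000 ticks per
trial, 10 seeds), cart pole at 500 training samples and 5 epochs, and the
generative protocols on 8×8 synthetic images with areas [64-32-32] (+ a
10-unit latent area) for ablation and [64-64] for variability, 600–800
epochs, 3–5 seeds. The full-scale 28×28 configuration is available through
the same functions.

# Known limitations

* The loose hierarchy restricts forward weights to the flow direction
  (plus skips); within-area recurrence beyond the local
  representation-error motif, thalamo-cortical routes, and Dale's law /
  signed error populations are not modelled.
* Full dynamical phaseless alignment learning of $B$ (noise-carried) is
  approximated by the transpose-plus-frozen-noise refresh.
* The closed-form steady-state oracle requires an acyclic error graph;
  cyclic error routing is simulateable but has no closed form here.
* Learning rates are task-tuned constants; no schedules, momentum or
  minibatching (batch size is 1 throughout, matching the protocol).
* With retrospective units the voltage-mismatch plasticity form is
  unusable for long trials (see above); the package makes the
  error-compartment form explicit rather than hiding the issue.
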