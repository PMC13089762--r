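# errnet — error-neuron cortical microcircuit networks

`errnet` is an R package for simulating and training a biologically
plausible implementation of error backpropagation: a phaseless,
multi-compartment rate-neuron model in which every cortical area holds a
population of **representation units** (predictions flow forward through
weights `W`) and a population of **error units** (errors are explicitly
projected backward through weights `B`). It is aimed at computational
neuroscientists studying how credit assignment could be realised by
cortical circuitry, and at machine-learning researchers interested in
learning rules that need no phases, no weight transport and no buffered
activations.

## The model in brief

Representation somata leak-integrate a prediction- and an error-receiving
compartment,

    C_m du/dt = -g_l u - g_rep (u - u_pred) - g_err (u - u_err),
    u_pred = Σ_k W r_k,   u_err = L_RE r_E,

and emit the *prospective* rate `r = φ(u + τ_r du/dt)`, which compensates
the membrane lag when `τ_r = τ_m` (fast inference) or retains it as
short-term memory when `τ_r < τ_m`. Error somata multiplicatively gate
backpropagated errors with the local activation derivative,

    C_m de/dt = -g_l e - g_den (e - [L_ER φ'(ŭ)] ⊙ Σ_m B r_E(m)),

with the output area comparing against a target rate through `g_nudge`.
Forward weights learn by an always-on delta rule,
`dW/dt ∝ [ŭ - (g_rep/g_tot) u_pred] r_preᵀ`, and feedback weights are set
to the padded transpose of the forward weights plus frozen uniform noise
after every tick (approximate phaseless alignment). In the weak-nudging
limit (`g_err → 0`) the settled updates recover the backpropagation
gradients of the equivalent layered network exactly; the equivalence,
including the conductance attenuation `g_rep/g_tot`, is implemented in
`as_ann()` and asserted in the test suite.

The package also ships the full benchmark suite used to exercise the
model — cart-pole distillation from an LQR teacher, delayed
match-to-sample (temporal XNOR), Yin-Yang classification, teacher-student
regression and class-conditioned image generation — plus reference
baselines (exact backpropagation, and a leaky recurrent network trained
with BPTT), alignment-angle metrics, and a noise-driven dendritic
reconstruction of `φ'(u)`.

## Worked example

Distil a random [4-2-1] teacher network into a microcircuit of the same
architecture:

```r
library(errnet)
set.seed(1)
task <- generate_teacher_student(complexity = 2)   # [4-2-1] teacher
net  <- ts_network(arch = c(4, 2, 1), eta = 2)
net
#> <mc_network: 3 areas [4-2-1], strict classifier>
#>   error units [4-2-1]; input area 1, target area 3
#>   2 forward block(s), 2 feedback block(s); dt = 0.01, T_pres = 0.2
#>   tau_m^r = 5.263; sigma_L = 0.3; feedback noise = 0.5

fit <- mc_fit(net, task$train, epochs = 200, eval_data = task$test,
              eval_every = 50)
fit
#> Trained error-neuron microcircuit
#> ...
#>   final train mse_loss: 0.000320674
#>   final test mse_loss: 0.000459439
```

The test loss is the mean over the 100 held-out samples of the summed
squared output error: after 200 epochs of phaseless, always-on learning
the circuit reproduces the teacher's input-output map to ~5e-4, four
orders below the target variance. The trained weights are ordinary
matrices:

```r
round(coef(fit)[["A3<-A2"]], 3)
#>        [,1]  [,2]
#> [1,] -1.013 1.011
```

`predict()`, `residuals()`, `plot()` (loss curves) and `simulate()`
(tick-by-tick voltage/rate trajectories) behave as for any fitted model
object. Experiment recipes with the reference parameter sets are
one-liners: `dms_network()`, `cartpole_network()`, `generative_network()`,
`yinyang_network()`, `ideal_bp_network()`; YAML experiment presets live in
`inst/extdata/configs/` and run through `run_experiment()` or the thin
CLI at `inst/scripts/errnet-cli.R` (subcommands `run`, `validate`,
`phi-demo`, `report`).

## Package layout

- `R/dynamics.R`, `src/mc_core.cpp` — the per-tick dynamics (pure-R
  reference and compiled core, asserted identical in tests)
- `R/plasticity.R`, `R/network.R` — learning rules, connectivity,
  ablation and variability protocols
- `R/fit.R` — the `mc_fit()` modelling surface and S3 methods
- `R/tasks.R`, `R/baselines.R` — task generators, backprop/BPTT
  references and metrics
- `R/phiprime.R` — dendritic reconstruction of activation derivatives
- `R/protocols.R`, `R/config.R` — experiment recipes, config validation,
  records
- `vignettes/error-microcircuits.Rmd` — model, assumptions, numerical
  choices and limitations
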