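---
title: "Modelling plantar soft-tissue stiffness from regional gait pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plantar soft-tissue stiffness from regional gait pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantarstiff)
```

## The problem

Plantar soft tissue — the fat pads, fascia and intrinsic muscles of the
sole — cushions impact and stores energy during gait. Its stiffness, in
N/m, is measured at rest with a handheld probe that taps the tissue and
records the damped natural oscillation; but clinically one wants to know
how the *loading pattern during walking* relates to that resting
stiffness. `plantarstiff` models that relationship: the mean pressure of
ten anatomical plantar regions over the stance phase (hallux, toes 2–5,
metatarsals 1–5, midfoot, medial and lateral heel) predicts the
soft-tissue stiffness, and a perturbation analysis attributes the
prediction to individual regions with a sign for the direction of their
influence.

## Measurement formulas

Two formulas connect raw recordings to the model's inputs and output.

**Regional mean pressure.** For a region's pressure samples
$F_1, \dots, F_n$ over the stance phase,
$F_{mean} = \tfrac{1}{n}\sum_i F_i$. `mean_regional_pressure()` averages
over *all* provided frames; windowing to heel-strike/toe-off is left to
the data producer, since the formula itself carries no window. Whether
values are region-aggregated force (N) or pressure (N/cm²) does not
matter downstream: min–max normalization removes the scale, so the unit
is a label.

**Oscillation stiffness.** The probe's damped oscillation yields peak
acceleration $a_{max}$ and tissue deformation $\Delta l$, giving
$S = a_{max}\, m_{probe} / \Delta l$. The deformation convention is the
one genuinely open choice here: we define $\Delta l$ as the displacement
excursion from trace start to the first local extremum of
$|s(t) - s(0)|$ — the peak of the first compression half-cycle — which
is unambiguous on traces that start at probe contact. The probe mass
default (0.018 kg) is the order of magnitude of handheld indenter
probes; it scales trace synthesis only and cancels in round-trip checks.

## The regression network

A three-layer, multi-input single-output backpropagation network maps
the normalized 10-vector of regional pressures to normalized stiffness:
10 input nodes, 13 hidden nodes and 1 output node. The hidden-layer
count comes from the empirical sizing rule implemented in
`hidden_node_count()`; the rule's printed form (`Input + Output + a`)
gives 13 at $a = 2$, and a square-root variant
(`round(sqrt(Input + Output)) + a`) is also provided because the
printed form is unusual for this family of rules — both are exposed and
neither is guessed to be "intended". Activations are tanh (hidden) and
linear (output), the standard regression pairing; sigmoid is available
by configuration. Features and target are min–max normalized to (0, 1)
*before* splitting (the pipeline's stated order; this leaks the
test-set extrema into the transform, so a strict fit-on-train workflow
is available by fitting the normalizer on the training subset).
A constant column makes the min–max map undefined and is a named error
rather than a silent pass-through.

Training is deterministic full-batch gradient descent on the MSE of the
normalized target: learning rate 0.01, at most 8000 epochs, early stop
at MSE $\le 10^{-6}$ (normalized scale, since training happens on
normalized data). No momentum, mini-batching, regularization or
validation-based stopping is used — the method is deliberately the
plain one. The flat genome layout
`[input→hidden weights (row-major by hidden unit), hidden biases,
hidden→output weights, output biases]` (length 157 for 10-13-1) is the
bit-exact contract between the network and the optimizer below.

## Hybrid PSO-GA initialization

Backpropagation from a random start is sensitive to initialization, so
the genome is first optimized by a particle swarm with an embedded
genetic algorithm. The fitness of a genome is the training-set RMSE of
its predictions. Per swarm iteration:

1. a standard PSO velocity/position update
   ($v \leftarrow wv + c_1 r_1 (p - x) + c_2 r_2 (g - x)$),
2. a real-coded GA run seeded from the current particle positions,
3. the GA's best individual replaces the swarm's *worst* particle
   (velocity reset to zero).

Core parameters: 30 iterations, $c_1 = c_2 = 4.5$, swarm size 5; GA
with 50 generations, population 5, crossover rate 0.4 and early-stop
accuracy $10^{-6}$ on per-generation best-fitness improvement. Learning
factors of 4.5 lie far outside the classical PSO stability region
($c_1 + c_2 \lesssim 4$ with inertia), so the implementation adds the
stabilizers such configurations need to remain finite: a linearly
decreasing inertia weight (0.9 → 0.4), velocities clamped to half the
position range, and reflecting bounds at ±1 (a natural weight scale for
normalized data). Without them the swarm diverges immediately; with
them the hybrid behaves as an explorer whose actual convergence is
driven largely by the GA injection. The GA operators are the common
real-coded set — tournament selection (k = 2), per-gene arithmetic
crossover, Gaussian mutation (sd = 0.1 of the position range, rate
0.1), elitism of one — each a configuration knob, since none is forced
by the method's description. The GA runs once per swarm iteration
(matching the per-iteration exchange strategy); seeding it from the
swarm means it refines the swarm's current region rather than
restarting blindly, and a fresh-random seeding mode exists for
comparison. The global-best trace recorded per iteration is
non-increasing by construction and is the convergence diagnostic.

## Evaluation and attribution

Predictions are inverse-normalized before any metric, so errors are in
N/m: mean bias error $\tfrac{1}{n}\sum(y - \hat y)$ (signed), RMSE, and
the relative error percentage $|y - \hat y|/y \times 100$ summarized by
maximum and mean. The absolute value in REP is a deliberate reporting
convention: the raw formula is signed, but max/mean summaries of signed
percentages are not meaningful magnitudes. (The MBE sign convention in
published tables of this kind can be ambiguous — a positive MBE under
$y - \hat y$ means *under*-prediction; we implement the formula exactly
as written and leave interpretation to the reader.)

Mean Impact Value attribution perturbs each *raw-scale* feature column
by ±10%, re-normalizes, predicts, inverse-normalizes and averages the
difference: $MIV_i = \tfrac{1}{n}\sum (P_{i1} - P_{i2})$ in N/m.
Perturbing on the raw scale matches the physical reading of "a 10%
pressure change"; the division by $n$ is read as the mean over samples
(the standard MIV definition). Contribution rates normalize absolute
MIVs to percentages summing to 100, keep each MIV's sign, and rank by
contribution with ties broken by region index. MIV is computed on the
full dataset by default (train-only by configuration) and is invariant
to output-bias shifts, which cancel in $P_{i1} - P_{i2}$.

## The synthetic cohort

No public dataset pairs regional walking pressures with resting plantar
stiffness, so the package ships a seeded generator that emulates the
*statistical* structure of such a study: 30 subjects × 5 trials × both
feet = 300 samples. Each subject draws a persistent regional loading
shift (between-subject sd = 10% of the regional mean, shared by both
feet), each trial adds 5% within-subject noise, and pressures are
truncated at zero. The true pressure–stiffness relationship is not
known from first principles, so the generator posits a transparent
ground truth — linear in regional pressure deviations with configurable
signs and magnitudes, plus an optional smooth metatarsal-3 × medial-heel
interaction — precisely so that recovery of signs and accuracy are
*testable properties* rather than articles of faith. Default signs are
positive for metatarsals 2–5 and both heel regions, negative for
hallux, toes, metatarsal 1 and midfoot (the direction pattern reported
for real cohorts); default magnitudes (0.4 N/m per N), intercept
(477 N/m) and noise (4 N/m) are calibrated analytically so the
simulated cohort stiffness is ≈ 477 ± 15 N/m, the scale reported for
healthy young adults with this device class. Observed stiffness is
clipped to the device range 70–1900 N/m and flagged, never dropped.
Each walking trial pairs with one stiffness draw by default; a
mean-of-5-repeats pairing mode is provided because either protocol is
plausible in practice.

The raw-signal generators close the measurement loop: stance series use
a smooth double-peaked loading template rescaled so temporal means
reproduce the tabular pressures to machine precision, and oscillation
traces are the closed-form underdamped solution
$s(t) = (v_0/\omega_d)e^{-\zeta\omega_0 t}\sin(\omega_d t)$ with
default damping ratio $\zeta = 0.05$, light enough that
$a_{max} m/\Delta l$ recovers the programmed stiffness to about 0.5%
(well within the 1% closure tolerance the tests assert).

What the generator does *not* emulate: gait dynamics, anatomy-driven
correlation between adjacent regions, heteroscedastic device noise,
foot-side asymmetry, or any nonlinearity beyond the single interaction
term. Passing tests therefore demonstrate that the pipeline recovers a
known statistical structure at realistic scale and noise — not that the
fitted coefficients of any real cohort are correct.

## Numerical and reproducibility choices

* One global seed fans out to per-stage seeds
  (`seed + 100003 × stage offset mod 2³¹−1`), so cohort generation,
  splitting and optimization are each independently reproducible and
  the stage-wise workflow is bit-identical to the one-shot pipeline.
* All JSON artifacts serialize doubles at 17 significant digits, which
  round-trips IEEE doubles exactly; CSV artifacts are for inspection
  and carry R's default 15 digits.
* The 8:2 split uses a seeded uniform permutation (`round(0.8 n)`
  training rows). Trial-random splitting is the default; the
  subject-wise mode exists because trial-random leaks subject identity
  across the split — with 10 correlated trials per subject the default
  test error is optimistic for subject-level generalization.
* Degenerate inputs fail loudly: empty training sets, constant columns,
  zero-valued REP denominators, flat oscillation traces and
  out-of-bounds sizing constants are all named errors.

## Scale of the shipped checks

The test-suite and acceptance-script runs use the study-scale design
(300 samples, 30 optimizer iterations, 8000 training epochs) for the
end-to-end checks — the full pipeline fits in a few seconds — and
reduced optimizer settings (3 iterations, 5 GA generations, 200 epochs)
for orchestration smoke tests where only plumbing is under test.
Property checks use 20–1000 random instances per invariant. On the
noise-free linear cohort the full pipeline reaches test-set mean REP
well under 3% and recovers all ten effect signs across seeds; with the
default noisy generator the mean REP stays near 1% and the final
optimizer fitness lands near 0.15 on the normalized scale.

## Limitations

The model is a point predictor with no uncertainty quantification; the
metrics are point values. The hybrid optimizer's printed learning
factors require the documented stabilizers and should not be read as
generically recommended PSO settings. MIV attributions are model-based:
they describe the fitted network, and transfer to physiology only as
far as the network generalizes.
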