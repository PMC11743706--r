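# plantarstiff

Interpretable modelling of plantar soft-tissue stiffness from regional
plantar pressure during walking.

Plantar soft tissue (heel fat pad, plantar fascia, intrinsic muscles)
cushions and powers the foot; its resting stiffness, measured in N/m
with a handheld oscillation probe, is a clinical marker for conditions
such as plantar fasciitis and diabetic foot. `plantarstiff` links that
resting stiffness to the *dynamic* loading of the foot: the mean
pressure of ten anatomical plantar regions over the stance phase
(hallux, toes 2–5, metatarsals 1–5, midfoot, medial/lateral heel)
predicts stiffness through a 10-13-1 backpropagation regression
network, and a Mean Impact Value (MIV) analysis attributes the
prediction to regions, with a sign for the direction of influence.

The modelling core:

* **Measurement formulas** — regional mean pressure
  `F_mean = (1/n) Σ F_i` and probe stiffness
  `S = a_max · m_probe / Δl` from damped-oscillation traces.
* **Preprocessing** — min–max normalization of features and target to
  (0, 1), seeded 8:2 train/test split, exact inverse transforms.
* **Hybrid PSO-GA initializer** — a particle swarm (30 iterations,
  c1 = c2 = 4.5, 5 particles) over the flat 157-weight genome; each
  iteration an embedded real-coded GA (50 generations, population 5,
  crossover 0.4) runs and its best individual replaces the swarm's
  worst particle. Fitness is training-set RMSE.
* **BP training** — full-batch gradient descent, learning rate 0.01,
  up to 8000 epochs, target MSE 1e-6 (normalized scale).
* **Evaluation** — MBE, RMSE and relative error percentage (max/mean)
  on inverse-normalized predictions, per train and test set.
* **MIV attribution** — perturb each raw feature ±10%, average the
  prediction difference, normalize absolute MIVs to contribution rates
  summing to 100%.
* **Synthetic cohort generator** — seeded 30 subjects × 5 trials ×
  both feet (300 samples) with a known linear pressure→stiffness ground
  truth calibrated to ≈ 477 ± 15 N/m, so every stage is testable
  without laboratory data.

## Worked example

```r
library(plantarstiff)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> Synthetic gait cohort: 300 samples (30 subjects x 5 trials x 2 feet)
#> Observed stiffness: 473.30 +/- 12.91 N/m (0 clipped)

res <- run_pipeline(pipeline_config(seed = 1),
                    out_dir = file.path(tempdir(), "demo"))
res$report
#> Model error report (N/m; REP in %)
#>    set   n      mbe  rmse rep_max rep_mean
#>  train 240 0.009491 4.396   2.800   0.7271
#>   test  60 0.580418 4.707   2.282   0.7929
res$miv
#> Mean Impact Value report (MIV in N/m, contribution in %)
#>        region    miv sign contribution rank
#>   medial_heel 11.474    +       15.456    1
#>  lateral_heel  9.907    +       13.345    2
#>  metatarsal_2  9.334    +       12.573    3
#>  metatarsal_1 -8.381    -       11.290    4
#>  metatarsal_4  8.237    +       11.096    5
#>  metatarsal_3  7.946    +       10.703    6
#>        hallux -6.438    -        8.672    7
#>       midfoot -5.471    -        7.370    8
#>  metatarsal_5  3.713    +        5.001    9
#>      toes_2_5 -3.335    -        4.492   10
```

Reading the output: the network predicts held-out stiffness with a mean
relative error of 0.79% (max 2.28%) and a bias of +0.58 N/m — i.e. test
predictions sit slightly below the true values on average. The MIV
table says heel and lateral-metatarsal pressures push predicted
stiffness up (+) while hallux, toe, first-metatarsal and midfoot
pressures pull it down (−); here the medial heel carries the largest
share (15.5%) of the total attribution. On this synthetic cohort the
recovered signs match the generator's programmed effect directions for
all ten regions.

`run_pipeline()` writes every artifact of a run — cohort CSV with a
config sidecar, normalizer and split JSON, optimizer convergence trace,
training loss history, model JSON, error report, MIV table and a
manifest with seeds and checksums — so any run is reproducible
bit-for-bit. The stages are also available piecemeal
(`generate_cohort()`, `as_dataset()`, `fit_normalizer()`,
`split_dataset()`, `initialize_network()`, `train_bp()`,
`evaluate_sets()`, `miv_report()`), and `plot()` methods render the
convergence trace and the signed contribution bars.

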