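# plantimp

Plants change their electrical impedance when their environment changes:
light drives ion transport, stomatal opening and transpiration, all of which
alter how tissue conducts alternating current. `plantimp` treats the plant
itself as the sensor. It simulates a swept-frequency bioimpedance monitor —
a square-wave source feeding a series resistor and a parallel RLC tank,
capacitively coupled to the plant, demodulated by a diode/RC envelope
detector — and the full analysis pipeline that infers the light state
("dark"/"light") from the recorded spectra. It is aimed at researchers in
plant electrophysiology and biosensing who want a tested, fully synthetic
testbed for this class of monitoring systems: every stage from circuit
physics to classifier attribution is reproducible from a seed, with no
measured data required.

The plant load is a Cole single-dispersion impedance

> Z(ω) = R∞ + (R0 − R∞) / (1 + (jωτ)^α),

whose parameters relax exponentially (lag τ_resp ≈ 5 min) toward
light- or dark-specific targets, with slow geometric baseline drift and
additive sweep noise. Each minute the instrument records a burst of
sweeps over 230 frequencies (20–249 kHz, 1 kHz steps, 1 ms dwell; 100 sweeps
≈ 23 s, 460 bytes per encoded sweep). The classifier is an LSTM (16 units)
over the burst's sweeps with additive attention pooling,

> e_t = vᵀ tanh(W h_t + b),  α = softmax(e),  c = Σ_t α_t h_t,

followed by a 16-unit ReLU layer (L2 1e-3, dropout 0.5) and a sigmoid
output, trained with Adam (lr 1e-3, batch 32, ≤100 epochs, early stopping
patience 10, reduce-on-plateau), after removal of the first 10 min after
every light switch, a chronological 60/20/20 split, and per-frequency
standardization fit on the training block. Cross-plant transfer is studied
by fine-tuning (all weights, lr 5e-4) on a parameter-shifted "second plant".
Integrated gradients explain predictions per time step and frequency. The
recurrent network, its backpropagation and Adam are implemented inside the
package (R matrix ops); gradients are verified against finite differences in
the test suite.

## Worked example

Twelve hours of synthetic data, trained and explained end to end:

```r
library(plantimp)
set.seed(42)

schedule <- generate_schedule(total = 720, min_phase = 60, max_phase = 180)
ds <- generate_dataset(schedule, default_plant_profile(),
                       acquisition_config(sweeps_per_burst = 20))
ds
#> <burst_dataset> 720 samples x 20 sweeps x 230 frequencies
#>   span 0..719 min | labels: dark=387, light=333 | profile: plant-A

kept  <- filter_transitions(ds, schedule, window = 10)
parts <- chronological_split(kept)
std   <- standardize(parts$train, val = parts$val, test = parts$test)

model <- build_model(model_config(), input_shape = dim(std$train$x)[2:3])
model <- train(model, std$train, std$val, training_config(seed = 1))
glance(model)
#> # A tibble: 1 × 5
#>   n_parameters epochs best_epoch best_val_loss val_accuracy
#>          16385    100        100        0.0112            1

preds <- predict(model, std$test)
mean(preds$predicted == preds$label)
#> [1] 1
```

Every test-block sample is classified correctly (`per_cycle_accuracy(preds,
schedule)` shows the two evaluated phases at accuracy 1.0). On a short
12-hour schedule the later blocks can be class-skewed —
`class_balance_report()` flags that here — which is why the study-scale runs
below use 48 h. Attribution then ranks the informative frequencies:

```r
x1 <- matrix(std$test$x[1, , ], nrow = 20)
iv <- feature_importance(integrated_gradients(model, x1, m = 50),
                         frequencies = dataset_frequencies(ds))
top_k_features(iv, k = 5)
#> # A tibble: 5 × 4
#>    rank index freq_hz importance
#>       1    18   37000  0.0000745
#>       2    22   41000  0.0000614
#>       3    29   48000  0.0000600
#>       4     6   25000  0.0000592
#>       5    26   45000  0.0000581
```

so for this model the decisive information sits in the 25–50 kHz region
around the loaded tank resonance, where the sweep responds most strongly to
the Cole parameters. `band_importance(iv)`, `autoplot()` methods and
`export_heatmap()`/`export_trends()` provide the standard figures;
`run_experiment()` orchestrates all of the above, including the cross-plant
fine-tuning scenario, from one seed.

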