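# capseeg

Automated detection of epileptic seizures in single-channel EEG with a
compact ("micro") capsule network.

## Who this is for

Researchers working on small-sample EEG classification — in particular the
canonical single-channel seizure corpus layout: five sets (A–E) of 100
plain-text ASCII files, one amplitude per line, 4096 samples per file at
173.61 Hz. Sets A/B are healthy scalp EEG (eyes open/closed), C/D
intracranial interictal EEG, and E ictal EEG from the seizure onset zone.
The standard benchmark cases are **AB vs E** (normal vs ictal), **C vs E**
and **D vs E** (interictal vs ictal), and **A vs C vs E** (three-class).

The package never downloads data. If you have the public corpus, point the
loaders at it; otherwise a built-in synthetic generator emulates the three
clinical states at the same file geometry so the entire pipeline runs
self-contained.

## The method

1. **Segmentation**: a fixed sliding window (default 1 s, zero overlap)
   cuts each recording into short segments; segments are z-scored with
   training-set statistics.
2. **Dimensionality expansion**: each 1-D segment of length *L* becomes a
   near-square matrix *A*<sub>m×n</sub> (row-major fill, zero-padded to the
   smallest *L′* ≥ *L* with factor pair *h*/*w* ≤ 2): 342 → (19, 18),
   178 → (15, 12).
3. **Micro-capsule network**: a 4×4 same-padded convolution (8 filters,
   ReLU), two stacked 4×4 valid convolutions (8 filters each), a reshape
   into 4-D **primary capsules** (312 of them for the 19×18 input) with the
   squash nonlinearity *v* = (‖*s*‖²/(1+‖*s*‖²)) · *s*/‖*s*‖, per-pair
   predictions *û*<sub>j|i</sub> = *u*<sub>i</sub>*W*<sub>ij</sub>, and
   **dynamic routing-by-agreement** (r = 3 iterations:
   *c*<sub>ij</sub> = softmax<sub>j</sub>(*b*<sub>ij</sub>),
   *s*<sub>j</sub> = Σ<sub>i</sub> *c*<sub>ij</sub>*û*<sub>j|i</sub>,
   *v*<sub>j</sub> = squash(*s*<sub>j</sub>),
   *b*<sub>ij</sub> += *û*<sub>j|i</sub>·*v*<sub>j</sub>) into one 16-D
   **label capsule** per class. A capsule's length is the probability its
   class is present. No reconstruction decoder; 42,136 trainable
   parameters in the binary configuration.
4. **Margin loss**, minimised with Adam (lr 5e-4, batch 32):
   *L*<sub>k</sub> = *p*<sub>k</sub> max(0, 0.9 − ‖*v*<sub>k</sub>‖)² +
   0.5 (1 − *p*<sub>k</sub>) max(0, ‖*v*<sub>k</sub>‖ − 0.1)².
5. **Protocol**: shuffle, 7:3 train/test split (stratified), three-fold
   cross-validation on the training portion, one model per fold, each
   evaluated on the shared test set; accuracy, sensitivity, and
   specificity (ictal positive) reported as mean ± sd over folds.

The network — forward pass, backpropagation, and Adam — is implemented in
vectorized base R; see the methods vignette
(`vignettes/capseeg-methods.Rmd`) for every design decision and numerical
choice.

## Worked example

```r
library(capseeg)

# synthetic surrogate corpus: sets A/B = background, C/D = interictal,
# E = ictal, same file geometry as the real corpus
sets <- gen_bonn_surrogate(synth_config(seed = 11), n_files_per_set = 8)

report <- run_case(sets, bonn_cases()$AB_vs_E,
                   segmentation_config(),          # 1-s windows -> 16x11 grid
                   train_config(epochs = 8, seed = 5))
print(report)
#> <metrics_report> case AB_vs_E (2 classes, 3 folds)
#>   accuracy      99.40 +/-  0.00 %
#>   sensitivity  100.00 +/-  0.00 %
#>   specificity   99.10 +/-  0.00 %
```

Each of the three folds trains its own network on two-thirds of the
training portion and is scored on the shared 30% test split; the numbers
are the mean ± sd across those folds, in percent. `report$histories` holds
per-epoch loss/accuracy curves, `report$confusions` the per-fold confusion
matrices, `write_report()` serialises everything to JSON/CSV.

With the real corpus on disk (one directory per set):

```r
sets <- list(A = load_set("bonn/A", "A"), B = load_set("bonn/B", "B"),
             E = load_set("bonn/E", "E"))
report <- run_case(sets, bonn_cases()$AB_vs_E,
                   segmentation_config(preset = "table1"),  # 342 -> (19,18)
                   train_config())                          # 400 epochs
```

## Command line

```sh
inst/cli/capseeg synth --config run.yaml --out data/
inst/cli/capseeg train --config run.yaml --data data/ --case AB_vs_E --out runs/
inst/cli/capseeg sweep --config run.yaml --data data/ --case AB_vs_E --out runs/
inst/cli/capseeg eval  --checkpoint runs/AB_vs_E_fold1.caps.json --data data/
```

`run.yaml` holds `segmentation`, `model`, `training`, `synth`, and `cases`
sections; unknown keys are rejected by name (see `?read_run_config`).

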