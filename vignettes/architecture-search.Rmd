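---
title: "Evolving compact U-shaped segmentation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving compact U-shaped segmentation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaunet)
```

## The problem

Binary biomedical segmentation — lungs or livers in CT slices, cell nuclei
in fluorescence microscopy — is dominated by U-shaped encoder–decoder
networks. The classic U-Net is hand-designed and heavy (about 31 million
parameters); for many binary organ-segmentation tasks a far smaller network
of the same shape performs comparably. `gaunet` automates that design
choice: a genetic algorithm (GA) searches a compact space of U-shaped
architectures and training recipes, scoring each candidate by briefly
training it and measuring validation pixel accuracy.

## The genome and its search space

A candidate is a ten-gene integer/real vector:

| gene | symbol | domain | meaning |
|---|---|---|---|
| `n_blocks` | B | 3–7 (odd) | total blocks: encoder + bottleneck + decoder |
| `first_filters` | C | 2, 4, 8 | filters in the first block; doubled per level |
| `kernel_size` | F | 3–7 | square convolution kernel |
| `activation` | A | 1–3 | ReLU / ELU / LeakyReLU |
| `pooling` | P | 1–2 | max / average, 2×2 stride 2 |
| `batch_norm` | BN | 0/1 | BN between each convolution and activation |
| `dropout` | D | 0/1 | rate 0.3 after each block |
| `optimizer` | O | 1–4 | SGD / RMSprop / Adam / Adamax |
| `learning_rate` | LR | [1e-4, 1e-3] | continuous, sampled log-uniformly |
| `batch_size` | BA | 4, 8, 16, 32 | training mini-batch |

Because the decoder mirrors the encoder around a single bottleneck block,
the total block count is `2d + 1` for depth `d` — necessarily odd. The
domain 3–7 therefore effectively contains {3, 5, 7}; `repair_genome()`
decrements an even draw by one. Repair also snaps any out-of-range gene to
its nearest allowed value, breaking ties toward the smaller value — a
deliberate bias toward cheaper architectures, in keeping with the
parameter-limiting goal of the search. The learning rate is treated as
continuous on its interval (the stated range gives no grid) and sampled
log-uniformly, the standard prior for learning rates.

We read the optimizer domain as the four codes 1–4; a "0 to 4" phrasing
would imply five values for four optimizers and is treated as inconsistent.

## Decoding and exact parameter accounting

`decode_architecture()` expands a genome into the layer plan: encoder
channels `C, 2C, …, C·2^(d−1)`, bottleneck `C·2^d`, mirrored decoder, skip
connections concatenating each encoder output into the same-level decoder
block, 2×2 stride-2 transposed-convolution upsampling, and a 1×1 sigmoid
head. Every convolution uses same-size padding; even kernels (4×4, 6×6) pad
the extra pixel on the bottom/right.

`count_parameters()` sums closed forms per layer — `k²·cin·cout + cout` per
convolution, `4·cin·cout + cout` per 2×2 transposed convolution, 4 per
batch-normalized channel (scale, shift, and the two running statistics),
zero for pooling/activation/concat/dropout. Three conventions matter and
were chosen because they are the only combination consistent with all four
published complexity figures at once:

* upsampling is a *parameterized* transposed convolution (parameter-free
  bilinear upsampling cannot reproduce any of the printed counts);
* batch-norm running statistics are included (total-parameter convention;
  trainable-only truncates the deepest genome to 0.206 M instead of
  0.207 M);
* millions are *truncated*, not rounded (148,825 would otherwise print as
  0.149 M, not the published 0.148 M).

Input channel counts are not stated per dataset in the source material; we
use 1 for the CT-like datasets and 3 for RGB microscopy, the assignment
under which all printed counts match exactly. Published reduction ratios
are reproduced on the printed-millions scale (e.g. 0.076/31.03 → 0.24%),
which is the only convention that matches all the stated percentages
simultaneously; `param_reduction()` implements it.

```{r}
arch <- decode_architecture(discovered_genome("lung"), in_channels = 1)
count_parameters(arch)
params_in_millions(count_parameters(arch))
param_reduction(count_parameters(arch), count_parameters(unet_baseline(1)))
```

## The evolutionary loop

`run_search()` implements a generational GA with elitist environmental
selection. Defaults follow the published setting: 5 generations, population
10, 5 elite parents, crossover rate 0.5, mutation rate 0.1, 20 training
epochs per fitness evaluation.

* **Fitness** is validation pixel accuracy at threshold 0.5 after short
  Dice-loss training with the genome's own optimizer, learning rate and
  batch size. Elite parents keep their cached fitness — retraining under a
  stochastic objective would break elitism's monotonicity guarantee.
* **Crossover** is single-point: with probability 0.5 a cut in 1–9 is drawn
  and the gene tails swapped; children are repaired.
* **Mutation** resamples each gene independently with probability 0.1. A
  literal "perturb the last gene" reading would only ever touch the batch
  size and could not diversify the population, so per-gene resampling at
  the stated mutation rate is used; this is a design decision, not an
  inference about the original implementation.
* **Offspring pairing**: the K sorted parents form successive overlapping
  pairs (1,2), (2,3), …, (K−1,K), yielding 2(K−1) offspring. This
  guarantees at least the L−K candidates environmental selection must admit
  under the default setting (8 ≥ 5) while honoring pairing of successive
  parents by fitness rank. A consequence is that K must be at least 2.
* **Environmental selection** forms the next population from the K best
  parents plus the best L−K offspring, so population size is constant and
  best fitness is non-decreasing.
* **Tie-breaks** everywhere are (fitness descending, id ascending), making
  every selection step deterministic.

Reproducibility: the master seed drives one R random stream for
initialization and GA operators; each candidate's training seed is a hash
of its genome folded with the master seed, so identical genomes train
identically and caching is sound.

## The built-in training engine

The package ships its own compact CNN engine (forward and backward passes
written against BLAS matrix products): convolution via shifted-slice
multiplication, 2×2 max/average pooling, non-overlapping 2×2 transposed
convolution, batch normalization, inverted dropout, the three activations,
sigmoid head, smoothed Dice loss, and the four optimizers with their usual
defaults (RMSprop rho 0.9; Adam 0.9/0.999 with bias correction; Adamax
infinity-norm; epsilon 1e-7). Gradients are verified against central finite
differences in the test suite.

Engine-specific choices:

* Samples are processed singly and gradients averaged per mini-batch, so
  training-mode batch normalization uses per-sample spatial statistics
  (as in instance normalization) with running averages (momentum 0.99,
  epsilon 1e-3) for inference. Parameter accounting is unaffected.
* Weights are Glorot-uniform, biases zero, seeded.
* The Dice loss uses smoothing constant 1 in numerator and denominator —
  the common stabilizer for empty masks; it is excluded from the reported
  Dice metric. LeakyReLU slope is 0.3 and ELU alpha 1, parameter-free
  defaults of the framework family these networks are usually built in.
* Dropout (when its gene is on) follows each block's second activation;
  block-level placement keeps the two-convolution block abstraction intact
  and adds no parameters. None of the published genomes enables it.
* Training divergence (non-finite loss) stops the run and degrades the
  candidate's fitness to 0 with a warning rather than an error, so one bad
  recipe cannot abort a search.

## Synthetic phantoms

`generate_dataset()` builds seeded organ-like phantoms: each mask is a
union of 1–3 random filled ellipses (semi-axes 6–20 px in a 64×64 frame),
rendered at foreground intensity 0.8 over background 0.2 with Gaussian
noise (sigma 0.05) clipped to [0, 1]; `channels = 3` replicates the
structure with independent per-channel noise. These defaults are the
package's desk-scale stand-in for the real CT/microscopy datasets: blob
topology and contrast are representative, while 64×64 keeps a whole search
affordable on one CPU (sizes are configurable up to real-data scale in
multiples of 8). `split_dataset()` applies the 80/20 train/test split with
10% of the training portion (at least one image) held out for validation,
by floor arithmetic on a seeded shuffle.

What the phantoms do *not* emulate: anatomical shape priors, intensity
inhomogeneity, unclear organ borders, touching nuclei, or varying image
sizes. Passing tests on phantoms therefore demonstrate that the search
machinery, engine, and metrics are correct and that discovered
architectures can learn a well-posed binary task — not that any specific
architecture will reach a particular score on real clinical data.

## Worked example

A deliberately small search (population 4, two generations, two epochs per
evaluation) on the default phantoms:

```{r, eval = FALSE}
ds <- generate_dataset(synthetic_config(seed = 7))
sp <- split_dataset(60, seed = 7)
fitness <- training_fitness(ds$images[sp$train], ds$masks[sp$train],
                            ds$images[sp$validation], ds$masks[sp$validation],
                            epochs = 2, master_seed = 7)
cfg <- ga_config(generations = 2, population_size = 4, n_best_parents = 2,
                 epochs_per_eval = 2, master_seed = 7)
res <- run_search(cfg, fitness)
res$log[, c("generation", "best_fitness", "mean_fitness", "evaluations")]
```

At these budgets fitness values are modest — two epochs barely move a
freshly initialized network — but the elitist log is non-decreasing and the
best candidate already segments above chance. Training a small decoded
network properly (10 epochs on noiseless phantoms) reaches a test Dice
above 0.98 in under a minute; the test suite asserts a conservative 0.8.

Metric note: the AUC is computed pixel-pooled within each image and
averaged across images (whether published AUCs pooled pixels globally is
not stated; per-image pooling matches how the other metrics are averaged).
Degenerate denominators (no predicted positives, single-class truth) return
0 or 0.5 with an `undefined` attribute instead of erroring, which matters
for all-background tiles.

## Limitations

* The engine is CPU-bound R; it is built for the package's desk scale
  (small images, sub-million-parameter networks), not for training at
  256×256 over hundreds of epochs.
* Single-class sigmoid heads only; no multi-class softmax, no 3D volumes,
  no attention/residual variants — the search space is deliberately the
  compact one described above.
* Fitness is single-objective (accuracy); parameter count enters only
  through the bounded search space, not the selection criterion.
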