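# mrseqopt

Automated, simulation-driven optimization of Cartesian MRI pulse sequences
described in a small domain-specific language (DSL).

Choosing an MRI sequence and protocol — RARE or EPI, which TE/TR, how many
measurements — requires expert knowledge of contrast mechanisms and artifact
behaviour. `mrseqopt` is aimed at MR physicists and methods researchers who
want to close that loop automatically: a clinical demand written in a
requirements DSL ("maximize grey/white-matter contrast, keep tissue SNR above
30, avoid ghosting") is turned into a constrained optimization over sequence
space, solved against machine-learned surrogates of a tissue-level MRI
simulation, and the result is emitted as sequence-DSL text.

## What is inside

* **Two DSLs.** A sequence DSL (echo type, readout type, pulses, TE/TR,
  trajectory, measurements, prescans, spoiling; unset fields take family
  defaults for RARE / SE-EPI / EPI / bSSFP) and a requirements DSL
  (`maximize "GWC"`, strict inequalities, `avoid`/`allow`/`have <quantifier>`
  statements).  Parsers, default expansion, a renderer with exact round trip,
  and a translation of vague wording into numeric bounds through a
  configurable ordinal dictionary.
* **Digital phantoms.** A 100 x 100 mm square brain-tissue phantom
  (CSF/GM/WM squares, a striped structure section, a filled homogeneity
  block; 4 spins/mm^2) and a circular motion/distortion phantom
  (2 spins/mm^2, uniform off-resonance, sawtooth translational motion).
* **A tissue-level isochromat simulator.** Magnetization is evolved through
  the full RF/relaxation schedule (prescans and repeated measurements, so
  steady-state effects are included); spatial encoding is applied analytically
  as Fourier phases, k-space is assembled per line, complex Gaussian noise is
  added, and magnitude images are reconstructed at 1 x 1 mm.
* **Twelve image-quality metrics.** Tissue contrasts (CGC/GWC/CWC), tissue
  SNR (Rayleigh-corrected background method), ghosting level, sharpness and
  homogeneity (Pearson correlation against the simulated target), motion and
  distortion sensitivity (PE shift scans), and acquisition time.
* **Surrogate learning.** A four-family parameter grid is simulated (four
  simulations per sequence), split 60/20/20 (three-way holdout), and one
  regressor per metric is tuned by random search under 10-fold
  cross-validation over SVR, kernel-weighted Minkowski kNN, and random
  forests; selection uses the test partition, final errors the validation
  partition.  A PCA summary of inputs and outputs is included.
* **Evolutionary optimization.** Real-valued genomes, line crossover,
  annealed Gaussian mutation, elitism + tournament selection; the fitness is
  `p_goal − Σ strict penalties − Σ vague penalties` with an exponential
  penalty `exp(a (p_m − c_m))` for violated artifact bounds; every candidate
  is repaired onto the nearest valid grid sequence before evaluation.

## Worked example

```r
library(mrseqopt)

# 1. a requirement: maximize grey/white contrast under SNR constraints
req <- read_requirement(system.file("extdata", "req_gwc.mrreq",
                                    package = "mrseqopt"))
problem <- translate_requirement(req)
problem
#> <optimization_problem> maximize gwc
#>   strict: snr_gm > 30
#>   strict: snr_wm > 30
#>   strict: snr_gm > snr_wm
#>   vague:  ghost < 0.05  [exp penalty]

# 2. simulate the reduced training grid and learn the surrogates (~1 min)
tab <- run_reduced_campaign(seed = 1)
nrow(tab)
#> [1] 182
models <- select_and_validate(split_table(tab, seed = 1),
                              hyperparameter_space(budget = 60), seed = 1)

# 3. evolutionary search over sequence space
res <- optimize_sequence(problem, models, sequence_grid_config(reduced = TRUE),
                         ea = ea_config(seed = 1))
round(res$predicted[c("gwc", "snr_gm", "snr_wm", "ghost")], 3)
#>    gwc snr_gm snr_wm  ghost
#>  1.042 32.195 30.994  0.068
all(strict_satisfied(problem, res$predicted, res$best_vector))
#> [1] TRUE
cat(render_sequence(res$best_spec))
#> define MRI sequence "repaired"
#>   using a "GradientEcho" with "EPIReadout".
#> Add gradient spoiling after segment.
#> ...
#> Specify timing parameters
#>   with TE 10
#>   and TR 1500.
#> ...
#> Specify measurements
#>   with count 3.
```

The search settles on a steady-state (3-measurement) EPI at short TE and long
TR: the SNR floor rules out the short-TR regions and repeated measurements
suppress the shot-to-shot transients that drive the ghosting penalty.

The returned sequence satisfies every strict constraint under the trained
surrogate's own predictions; the fitness trace (`res$trace`) is
non-decreasing because elites are preserved.

A command-line wrapper with `generate-data`, `train`, `optimize` and
`simulate` subcommands is installed at `inst/cli/mrseqopt` (see
`?run_cli`).

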