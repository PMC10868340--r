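# indelfit

`indelfit` determines which indel length distribution best characterizes a
multiple sequence alignment (MSA), given its rooted phylogeny. It is aimed
at molecular evolution researchers and bioinformaticians who need a
statistically grounded alternative to gap counting — gap blocks are not
indel events, and the alignment itself was inferred under a gap-length
assumption that biases naive counts.

Six candidate models are compared: three length-distribution families —
Zipf (discrete power law, P(k) ∝ k⁻ᵃ), geometric, and Poisson, each
truncated at 150 sites and renormalized on support {1, …, 150} — crossed
with two variants: SIM (insertions and deletions share one rate and one
length distribution) and RIM (independent parameters per event type).
Selection is by rejection-based approximate Bayesian computation:

1. draw indel models from uniform priors (root length anchored on the
   alignment's shortest/longest ungapped sequence lengths; log₁₀ total
   rate in [−4, −1]; log₁₀ insertion/deletion ratio in [−1, 1]; mean
   indel length in [1.5, 25] sites, inverted to each family's native
   parameter);
2. simulate a "true" MSA for each draw with a Gillespie indel process
   along the tree, including an edge correction that keeps the per-site
   deletion rate uniform across positions;
3. reduce every MSA to 27 gap-pattern summary statistics (block and
   unique-gap counts by length class carry most of the family signal);
4. optionally correct the simulated statistics for the bias the empirical
   aligner introduces, using a regression trained on realigned
   simulations (MAFFT by default);
5. accept the k = 100 simulations nearest to the empirical statistics
   under a Mahalanobis distance and classify by the modal model label;
   grouped SIM+RIM counts / k estimate the posterior support per family;
6. test absolute fit with posterior predictive p-values: the adequacy
   match (AM) score is the fraction of the 27 statistics whose empirical
   value has a percentile rank inside [0.025, 0.975] in 10,000 predictive
   simulations from the selected model.

## Worked example

Simulate a dataset with a known truth (geometric-SIM, mean length 2.5,
total rate 0.045 events/substitution/site, root length 950) on a 30-taxon
tree of total branch length 2, then classify it with desk-scale reference
tables (5,000 simulations per model; the full-scale default is 500,500):

```r
library(indelfit)

tree <- make_tree(30, 2, "coalescent", seed = 11)
geom <- length_distribution("geometric", parameter_for_mean("geometric", 2.5))
truth <- indel_model("geometric", "SIM", 0.045, 0.045, geom, geom,
                     root_length = 950)
set.seed(1)
msa <- emit_residues(simulate_msa(tree, truth), "dna")

config <- pipeline_config(n_per_model = 5000, k = 100,
                          n_predictive = 1000, seed = 7)
report <- run_classify(msa, tree, config, out_dir = "indelfit_out")
```

Output (about 5 minutes on one CPU):

```
selected model:  geometric-SIM
family support:  zipf 0.26   geometric 0.51   poisson 0.23
AM score:        0.704
posterior (accepted draws of geometric-SIM):
  root_length       mean 939.1   q05 781.0   q95 1102.0
  log10_total_rate  mean -1.53   q05 -2.09   q95 -1.05
```

Reading it: 51 of the 100 accepted simulations came from a geometric
model, so the geometric family is selected with posterior support 0.51 —
correct, and the posterior means bracket the generating values
(root length 950, log₁₀ rate −1.5). The AM score of 0.704 means 19 of the
27 statistics fall inside the central 95% of their predictive
distributions; `report$adequacy$flagged` lists the ones that do not.
At these desk-scale table sizes the accepted neighborhood is much sparser
than at the full scale, so supports are flatter and family calls near the
geometric/Zipf and geometric/Poisson boundaries are noisier — see the
methods vignette for the scaling discussion.

A command-line front end with `simulate`, `stats`, `classify`,
`adequacy`, `selftest`, and `fixtures` subcommands is installed at
`system.file("cli", "indelfit.R", package = "indelfit")`.

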