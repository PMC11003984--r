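# coregrn

Data-driven inference, optimization, and perturbation modeling of core
gene regulatory networks (GRNs).

Given two-group expression data (e.g. disease vs control), a curated
TF→target database, a TF–gene binding-probability table derived from
chromatin accessibility, and ranked TF lists from external selection
methods, `coregrn`:

1. **enumerates candidate TF–TF networks** over a hyperparameter grid
   (binding threshold, TFs per list, activity-correlation cutoff) — an
   edge `A → B` requires database support and a strong Spearman
   correlation between the TFs' inferred *activities*, with the
   correlation sign setting activation vs inhibition;
2. **simulates each candidate** with an ensemble of ODE models with
   randomly sampled kinetics, using shifted-Hill regulation

   dY/dt = G_Y / Πλ⁺ · Π Hs(X_i, X_iY₀, n, λ) − k_Y·Y,  Hs(X) = λ + (1−λ)/(1+(X/X₀)ⁿ);

3. **selects the optimal network** by a combined ranking of *accuracy*
   (fraction of simulated models assignable to an experimental state by
   nearest-sample distance against a gene-shuffle permutation null) and
   *flexibility* (mean shift of the two-state model proportions over all
   single-gene knockdowns);
4. **screens in-silico knockdowns** (95% production-rate reduction,
   single TFs and pairs of the strongest destabilizers), mapping the
   perturbed ensembles to states with a ridge classifier trained on the
   unperturbed models, with chi-squared significance and PCA
   projections; TFs are annotated with their most representative
   pathway by Fisher's exact test on regulon–pathway overlap.

A first-class synthetic-data module plants a bistable two-module GRN
with known edges, two separated expression states, a noisy binding
table, and a curated database with dropout/spurious entries, so the
whole pipeline can be exercised and validated without any external
data.

Intended users: computational/systems biologists who have two-state
transcriptomics plus regulatory priors and want a mechanistic,
simulatable core circuit rather than a global regulatory map.

## Worked example

Everything below is synthetic and runs in about two minutes:

```r
library(coregrn)

sys  <- make_planted_system(seed = 17)      # 20 TFs, 2 modules, 66 edges
expr <- emit_expression(sys)                # 11 control + 9 case samples

cfg <- pipeline_config(
  expr = expr, curated = sys$curated, binding = sys$binding,
  ranked_lists = emit_ranked_tf_lists(sys),
  binding_grid = 0.1, k_grid = 20, cutoff_grid = c(0.3, 0.5),
  n_models = 1000, n_null = 500, stability_repeats = 0, seed = 17)

opt <- run_optimize(cfg)
print(opt)
#> grn_optimization: 2 candidates (1 unique simulations); optimal b0.1_k20_c0.3:
#>   20 TFs, 90 edges, accuracy 0.466, flexibility 0.0161

per <- run_perturb(cfg, opt)
print(per)
#> grn_perturbation: 65 KD conditions (20 singles, 45 pairs);
#>   42 significant pairs (chi-squared p < 0.05)

head(per$destabilizers[, c("kd", "m_control", "m_case", "chisq_p")], 3)
#>     kd m_control    m_case      chisq_p
#> 1 TF15 0.6652935 0.3347065 2.507230e-24
#> 2 TF18 0.6321244 0.3678756 4.176539e-18
#> 3 TF19 0.5903866 0.4096134 9.674094e-12
```

Reading the output: the optimizer kept 2 candidate networks (identical
topology, so one simulation), and the selected network contains all 20
planted TFs.  Accuracy 0.466 means 46.6% of the 1000 random-kinetics
models land close enough to a real sample's activity profile to beat
their own gene-shuffled null at α = 0.05.  In the knockdown screen the
top destabilizers are module-B TFs (the planted case-state drivers):
knocking down `TF15` moves the ensemble to 66.5% control-state models,
against a chi-squared p of 2.5e-24 for the shift.

One candidate network can also be handled directly:

```r
net <- sys$network
ens <- simulate_ensemble(net, n_models = 1000, seed = 1)
act <- infer_activity(expr, build_merged_db(sys$curated, sys$binding, 0.1,
                                            genes = rownames(expr$expr)),
                      sys$tfs)
asn <- assign_states(ens, act[net$nodes, ], expr$labels, seed = 1)
accuracy(asn); state_proportions(asn)
```

A command-line front end with subcommands (`synth`, `build-db`,
`activity`, `enumerate`, `simulate`, `optimize`, `perturb`, `annotate`,
`run-all`) is installed at:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/coregrn.R", package = "coregrn"))')" synth --seed 17 --out fixtures/
```

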