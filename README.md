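# erconsensus

Consensus modeling of estrogen receptor (ER) activity predictions.

Risk assessors need to prioritize thousands of environmental chemicals for
costly ER testing. Many independently developed QSAR and docking models can
each call a chemical an active/inactive binder, agonist or antagonist — none
reliably alone. `erconsensus` implements the full pipeline for combining
such models into weighted consensus calls: chemical structure curation to a
unique QSAR-ready set, harmonization of noisy multi-source literature
activity records into reference sets, per-model scoring on stratified
chemical subsets, score-weighted categorical and potency consensus with
post-hoc consistency corrections, and a seeded synthetic-data generator so
that every stage is testable without external data.

## The method in brief

Each model *m* is evaluated by sensitivity, specificity and balanced
accuracy `BA = (sens + spec)/2` on six chemical subsets (HTS training data
minus the ambiguous AUC band [0.01, 0.1); all literature chemicals; ≥ 2
sources; without very-weak actives; inside the model's applicability
domain; all filters combined), and summarized by two scores:

    score_1 = (N_pred / N_total) · (1/5) · Σ_{i∈2..6} BA_i · n_pred_i / n_i
    score_2 = (BA_HTS + BA_all_filters) / 2

For each chemical, the mean `score_2` of the models calling it active is
compared with the mean of those calling it inactive; the higher mean wins.
Potency consensus uses weights `w_j = score_j / Σ_k score_k` over the n
predicting continuous models and the level `C = Σ_j w_j · s(P_j)` on the
class-score scale (inactive 0, very weak 0.25, weak 0.5, moderate 0.75,
strong 1), rounded to the nearest class. AC50 class boundaries are
0.09 / 0.18 / 20 / 800 µM. Four correction rules then reconcile the
categorical and quantitative layers and force agonist/antagonist actives to
be active binders; potency for newly reclassified actives comes from the
positive model concordance (strong ≥ 0.9, moderate ≥ 0.75, weak ≥ 0.6, else
very weak).

See `vignettes/consensus-pipeline.Rmd` for the complete account of the
model, the policy defaults and the design decisions.

## Worked example

Curation merges duplicates across salt forms and stereo/tautomer variants
and keys everything by InChI:

```r
library(erconsensus)
recs <- data.frame(
  record_id = c("bpa", "bpa_salt", "des_e", "des_z", "nacl"),
  smiles = c("CC(C)(c1ccc(O)cc1)c1ccc(O)cc1",
             "CC(C)(c1ccc(O)cc1)c1ccc([O-])cc1.[Na+]",
             "CC/C(=C(\\CC)c1ccc(O)cc1)c1ccc(O)cc1",
             "CC/C(=C(/CC)c1ccc(O)cc1)c1ccc(O)cc1",
             "[Na+].[Cl-]"))
res <- curate(recs)
print(res$report)
#> Structure curation report
#>   input records : 5
#>   output structures: 2
#>   merged duplicates: 2
#>   removals:
#>     inorganic                1
res$structures[, c("canonical_smiles", "molweight", "merged_ids")]
#>                    canonical_smiles molweight   merged_ids
#> 1     CC(c1ccc(cc1)O)(c1ccc(cc1)O)C  228.2863 bpa;bpa_salt
#> 2 CCC(=C(c1ccc(cc1)O)CC)c1ccc(cc1)O  268.3502  des_e;des_z
```

The sodium salt of bisphenol A is desalted, neutralized and merged with the
parent; the E/Z pair of diethylstilbestrol collapses after stereo removal;
sodium chloride is removed as inorganic.

A full pipeline run on a seeded synthetic study (500 chemicals, 10 models):

```r
cfg <- run_config(sim = sim_config(n_chemicals = 500, n_models = 10, seed = 42),
                  seed = 42)
run <- run_pipeline(cfg)
head(run$model_scores[run$model_scores$activity_type == "binding" &
                      !run$model_scores$is_continuous,
     c("model_id", "ba_toxcast", "ba_lit_all", "score_1", "score_2")], 4)
#>                   model_id ba_toxcast ba_lit_all score_1 score_2
#> binding.1 binding_model_01      0.742      0.667   0.668   0.744
#> binding.2 binding_model_02      0.860      0.723   0.714   0.798
#> binding.3 binding_model_03      0.720      0.663   0.592   0.726
#> binding.4 binding_model_04      0.778      0.693   0.483   0.746
```

Each row is one simulated model: its balanced accuracy on the HTS-style
training reference and on the literature reference, the coverage-weighted
`score_1` and the accuracy-focused `score_2` that weights the consensus.
The stratified report shows how agreement with the literature reference
improves for chemicals with more independent sources (sensitivity 0.905 at
≥ 1 source rising to 1.000 at ≥ 4 in this run), and the correction log
counts reclassifications per rule:

```r
table(run$correction_log$activity_type, run$correction_log$rule)
#>                1   2   3   4
#> agonist      103  38  74   0
#> antagonist   133  32  86   0
#> binding       88  58  66 298
```

## Command line

A thin CLI over the package functions lives at `inst/cli/erconsensus.R`
with subcommands `curate`, `simulate`, `build-eval` and `run`, e.g.

```sh
Rscript inst/cli/erconsensus.R curate --in chemicals.smi --format smiles --out curated/
Rscript inst/cli/erconsensus.R run --seed 42 --n-chemicals 2000 --out run1/
```
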