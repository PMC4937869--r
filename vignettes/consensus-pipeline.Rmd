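---
title: "Consensus modeling of estrogen receptor activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus modeling of estrogen receptor activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erconsensus)
```

## The problem

Tens of thousands of man-made chemicals have never been tested for
estrogen-receptor (ER) mediated activity. In silico screening combines many
independently developed QSAR and docking models — each predicting whether a
chemical binds ER, activates it (agonist) or blocks it (antagonist) — into a
single prioritization call per chemical. No individual model is reliable
enough on its own; the premise of consensus modeling is that a score-weighted
combination, evaluated against both high-throughput screening (HTS) data and
a literature-derived reference corpus, is.

`erconsensus` implements the full pipeline around that idea:

1. **Structure curation** — turning heterogeneous SDF/SMILES inputs into a
   unique, QSAR-ready structure set keyed by standard InChI.
2. **Reference building** — harmonizing noisy multi-source literature
   activity records into categorical (active/inactive) and five-level
   potency references.
3. **Model scoring** — evaluating each prediction set on six chemical
   subsets and summarizing it in two balanced-accuracy scores.
4. **Consensus and corrections** — score-weighted categorical and potency
   consensus with four post-hoc consistency rules.
5. **Synthetic data** — seeded generators that emulate the statistical
   structure of all of the above, so every stage is testable end to end
   without external data.

## Structure curation

The workflow applies, in order: parsing with a valence check; removal of
carbon-free (inorganic) structures; desalting; removal of structures above
1,000 g/mol (strictly greater than — a structure at exactly the cutoff is
kept); standardization; InChI-based duplicate merging; and removal of
metal-containing structures. Chemistry primitives are delegated to OpenBabel
via ChemmineR/ChemmineOB; the workflow logic is this package's.

Design choices that the workflow leaves open, resolved here once:

* **Valence checking.** OpenBabel accepts hypervalent atoms silently, so a
  small valence table is enforced at parse time (C ≤ 4, N ≤ 5 — admitting
  the neutral hypervalent notation of nitro/azide groups — O ≤ 3, halogens
  and H ≤ 1, B ≤ 4; hypervalent S and P are legitimate and unconstrained).
  Records that fail are dropped and logged; no online structure repair is
  attempted (a resolver can be plugged in front of `curate()`).
* **Desalting tie-breaks.** "Largest organic fragment" means: most heavy
  atoms among carbon-containing fragments; ties broken by molecular weight,
  then by lexicographically smallest canonical SMILES. Deterministic by
  construction.
* **Neutralization** uses OpenBabel's hydrogen-add/remove neutralization:
  charges that cannot be balanced this way (quaternary ammonium) legitimately
  remain.
* **Tautomer scope.** A fixed rule list — enol→keto, enamine→imine,
  ynol→ketene, applied to exhaustion in that order, lowest atom index
  first — plus SMILES-level unification of nitro and azide mesomers. The
  rules never touch aromatic-ring atoms (phenol is a fixed point) and are
  only attempted on charge-free molecules, because the SDF container used
  for the graph edit does not carry formal charges. Residually charged
  species rely on InChI normalization, which is the deduplication key
  anyway. Broader tautomer enumeration is deliberately out of scope:
  reproducibility over completeness.
* **Stereochemistry** is removed entirely (tetrahedral and double-bond), so
  enantiomers and E/Z pairs always merge.
* **Metal filter.** The allowed element set is H, B, C, N, O, F, Si, P, S,
  Cl, Se, Br, I; retention of the metalloids Si/Se/B is a configuration
  switch (`keep_metalloids`). Whether aromatization precedes InChI
  generation is immaterial for deduplication (InChI normalizes); canonical
  SMILES output is produced after aromatization.

Every removal is logged once, under the first step that triggered it, and
the report satisfies `n_input = n_output + removals + merged duplicates`.

## Reference sets from literature records

Records are first harmonized: in vivo and cytotoxicity entries dropped;
proliferation assays called active above 125% proliferation (a policy knob);
concentrations converted to micromolar by exact powers of ten — mass-per-
volume units are ambiguous and dropped; inactive records assigned the 1 M
sentinel (`1e6` µM).

The categorical reference applies three rules per chemical and activity
class: (1) if the minority fraction of source calls strictly exceeds 20%,
the group is removed (an exactly-20% minority survives with the majority
call — the rule says *exceeded*); (2) an active agonist or antagonist is an
active binder when binding is unobserved; (3) a chemical inactive as both
agonist and antagonist is an inactive binder when binding is unobserved.
Propagation never overwrites an observed binding call, and propagated rows
carry the maximum source count of the groups they derive from.

The potency reference bins each AC50 into five classes —
strong < 0.09 µM ≤ moderate < 0.18 µM ≤ weak < 20 µM ≤ very weak ≤ 800 µM <
inactive — maps classes to scores {0, 0.25, 0.5, 0.75, 1}, averages the
scores across sources, and maps back (strong > 0.75 ≥ moderate > 0.5 ≥ weak
> 0.25 ≥ very weak > 0 = inactive). Boundary sides are half-open on the
concentration scale except very weak's inclusive 800 µM upper bound, so
"higher than 800" is inactive. The log10-median of the source AC50s is
computed and stored as a descriptive field but does not drive the class:
the mean-score path is the classing convention here, and both are emitted
so either convention can be compared downstream.

## Model evaluation

Each model is evaluated on six subsets: (1) HTS training chemicals excluding
those whose activity-relevant AUC score falls in the ambiguous [0.01, 0.1)
band (the band applies to the AUC of the model's own activity class); (2)
all literature reference chemicals; (3) those with ≥ 2 sources; (4) subset 2
minus very-weak actives; (5) subset 2 inside the model's applicability
domain, identical to subset 2 when no AD was supplied; (6) the intersection
of 3–5. Training chemicals are *not* removed from literature subsets.

Balanced accuracy (BA) is the mean of sensitivity and specificity; a metric
with an empty margin is undefined (`NA`), never coerced to 0.5 or 0. The two
summary scores are

* `score_1 = (N_pred / N_total) · (1/5) · Σ_i BA_i · (n_pred_i / n_i)` over
  subsets 2–6 — favoring wide-coverage models (an undefined subset BA
  contributes zero and is logged);
* `score_2 = (BA_HTS + BA_all_filters) / 2` — favoring accurate models
  regardless of coverage.

Continuous (potency) models are mapped through the five classes and scored
by the unweighted mean of the five one-vs-rest BAs on literature subsets
(the multiclass aggregation is not prescribed anywhere authoritative; the
unweighted mean is this package's choice), and by the binary
active/inactive BA on the HTS subset, where only AUC-derived binary
activity exists.

## Consensus and corrections

For each chemical, the mean `score_2` of models calling it active is
compared with the mean of models calling it inactive; the higher mean wins.
An exact tie resolves as active: the stated purpose of the downstream
corrections is to reduce false negatives for prioritization, and the tie
rule follows that philosophy. Concordance is the fraction of predicting
models on each side; the pair sums to 1. Potency consensus weights are
model scores normalized to sum 1, the consensus level is the weighted mean
class score, and the consensus class is the nearest class score with
half-way levels rounded toward the more potent class (conservative for
screening).

The four correction rules run in one pass — agonist, antagonist, then
binding; rule 4 last:

1. categorical-active ⇒ quantitative-active, potency from positive
   concordance (strong ≥ 0.9 > moderate ≥ 0.75 > weak ≥ 0.6 > very weak);
2. quantitative-active with ≥ 3 raw active categorical calls ⇒
   categorical-active;
3. quantitative-active with < 3 active calls ⇒ quantitative-inactive;
4. active agonist or antagonist ⇒ active categorical binder, binding potency
   equal to the agonist/antagonist potency — the more potent of the two when
   both are active (the both-active case is not prescribed; the more potent
   class is the screening-conservative choice).

Rule 3 exempts chemicals whose categorical consensus is active: as literally
stated it would undo rule 1 on every pass for actives with fewer than three
active callers, and the pass would never reach a fixed point. With the
exemption one pass is idempotent — a property the tests assert — and the
false-negative-averse intent is preserved. "At least three models" counts
raw active calls, not score-weighted ones. Chemicals predicted by zero
models are emitted as `not_predicted`, never silently dropped.

## The synthetic world

The generators emulate the statistical structure of the study inputs:

* ~10% active prevalence for binding; agonist (50%) and antagonist (25%)
  activity nested inside binding activity, so the correction rules are
  exercised non-trivially and the antagonist class is unbalanced;
* active log10 AC50 uniform on [−2, 3] log10 µM, spanning all five potency
  classes;
* per-model sensitivity/specificity/coverage drawn from configured ranges,
  with calls conditionally independent across models given the truth;
* per-chemical detection probability graded in potency,
  `sens + 0.25 · (class score − mean class score among actives)` with the
  gradient shrunk (never clamped) to keep probabilities in [0, 1]: potent
  actives are easier to detect, as observed for real model ensembles, while
  the centering preserves the marginal sensitivity exactly — so parameter
  recovery within binomial error still holds;
* literature source counts from a geometric distribution (mean 3, truncated
  at 20), per-source false-positive/false-negative flips, lognormal spread
  of reported AC50s, a mixed unit vocabulary (M/mM/µM/nM) that round-trips
  through the unit converter, plus proliferation-percent records and
  in vivo/cytotoxicity decoys for the cleaning rules;
* HTS-style AUC scores: zero for inactives (a flat concentration–response
  carries no area), linear in log10 AC50 from 1 down to 0.1 for actives,
  with Gaussian noise and a configurable fraction forced into the ambiguous
  [0.01, 0.1) band;
* synthetic chemical keys are format-valid InChI-shaped strings derived
  from a counter; a separate 50-molecule real-SMILES fixture (salts,
  stereoisomer and tautomer pairs, an organometallic, a > 1000 g/mol
  alkane) exercises the actual curation chemistry.

Each generator draws from its own stream derived from the master seed, so
adding a generator never perturbs existing draws, and everything is
bit-reproducible under (configuration, seed).

**What the synthetic world does not emulate.** Real participant models share
training data and descriptor families, so their errors are strongly
*correlated*; the generator's models err independently given the truth.
This matters for one documented behavior: the higher-average-score
consensus rule decides split votes by comparing the mean scores of two
modest samples of similar model scores, which is nearly a coin flip when
disagreement is driven by independent noise. With correlated ensembles the
rule inherits the concordance structure and behaves like weighted
agreement; with independent errors it does not, and the consensus balanced
accuracy on the synthetic world sits *below* the median individual model's
(the property test stating the opposite dominance is retained and fails,
deliberately — see the test suite). Passing tests on this world therefore
validate the mechanics and bookkeeping of the pipeline, not the claim that
this consensus rule improves on its members for arbitrary ensembles.

## Numerical and testing choices

All policy numbers live in `run_config()` / `sim_config()` with the
defaults stated above; nothing numeric is hard-coded elsewhere. Metrics are
compared with published worked examples at 2-decimal rounding. Test problem
sizes were chosen to keep the full suite in the minutes range: 100
replicates of 2,000 chemicals × 15 models for ensemble-level properties, 50
replicates of 500 chemicals for the source-count stratification trend, and
a few hundred chemicals for pipeline integration checks. The acceptance
script (`scripts/acceptance.R`) runs the full pipeline on a 2,000-chemical
synthetic study and reports the quantities it computes; it derives all
randomness from its `--seed` argument.

## Known limitations

* Curation relies on OpenBabel's aromaticity and InChI implementations;
  structures OpenBabel cannot sanitize are dropped and logged rather than
  repaired.
* The tautomer rule list covers the named classes only; exotic tautomerism
  (e.g. ring-chain) is out of scope.
* The evaluation assumes a single reference per chemical and class;
  species- or subtype-specific activity differences are not modeled.
* The consensus rule's behavior under independent model errors is a
  structural property of the rule, not of this implementation — see above.
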