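---
title: "Confidence-stratified hazard triage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-stratified hazard triage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Industrial chemical inventories — here modelled on the substances used in
the leather and textile industry — contain thousands of substances, most of
which have no authoritative assessment for the regulatory hazard endpoints
that matter for safety screening: CMR (carcinogenic, mutagenic or toxic to
reproduction), endocrine disruption (ED), and the environmental endpoints
PBT and vPvB. Public sources (ECHA's CLP/REACH/SVHC listings, registration
dossiers, Pharos, curated reference databases) each cover a sliver of the
inventory, disagree occasionally, and leave the large majority of
(substance, endpoint) slots empty — in the inventory regime this package
emulates, roughly 84% of slots are uninformed.

`toxtriage` implements the desk-scale part of a triage strategy for that
situation: integrate what the sources do say into one conservative label
per slot, fill as many empty slots as possible with *in silico* predictions
that carry explicit reliability estimates, and use those estimates to
decide which predictions to trust and which compounds to send to the lab.

## Pipeline overview

1. **Registry** (`registry()`, `register_substance()`): substances are keyed
   on CAS-RN, the one identifier available for mixtures and proprietary
   substances that have no resolvable structure. CAS checksums are enforced
   by default (`validate_cas()`); structure conflicts for one CAS raise a
   typed condition rather than overwriting.
2. **Curation** (`curate_registry()`, `select_modelable()`): every SMILES is
   parsed and valence-checked, then classified into one of ten categories
   (organic, organic salt, organometallic, peptide, inorganic, inorganic
   salt, inorganic metal, and the three no-sanitizable variants). Only
   organics, organic salts (desalted to their largest organic fragment) and
   peptides are modelable; everything else is excluded with a recorded
   reason, never silently dropped.
3. **Integration** (`integrate_all()`): source-level hazard annotations are
   mapped to endpoints through an editable configuration table and resolved
   into YES / NO / Pending / NoInformation by a fixed precedence
   (ECHA core -> ECHA dossier tier -> reference database -> Pharos), with
   positives beating negatives within any tier.
4. **Dataset building** (`extract_training_set()`, `oversample()`,
   `partition_ensemble()`): YES -> 1, NO -> 0; for CMR, Pending also codes 1
   (if a substance might be CMR, it is treated as CMR). NoInformation
   substances are never trained on — they are the prediction set.
5. **Conformal QSAR** (`fit_conformal()`, `predict()`): Mondrian inductive
   conformal random forests over 2048-bit path fingerprints.
6. **Read-across** (`rax_infer()`): the fallback when a class is essentially
   empty (the ED regime), inferring positivity from a Tanimoto-similar
   annotated positive.
7. **Accounting and validation** (`account()`, `select_validation_set()`,
   `combine_assays()`, `compare_predictions()`): before/after bookkeeping
   with a high-confidence stratum, and reliability-ranked candidate
   selection for prospective laboratory validation.

## The conformal model

For a binary endpoint the training set is split 70/30 (stratified,
seed-deterministic) into a proper-training part and a calibration part. A
probability random forest (`ranger`, 500 trees, `sqrt(d)` features per
split, no depth limit, one thread for reproducibility) is grown on the
proper part. The nonconformity score of a record for class $c$ is
$\alpha_c(x) = 1 - \hat p(c \mid x)$. Calibration scores are kept per class
(*Mondrian* calibration), and a query's p-value for class $c$ is

$$p_c = \frac{\#\{\alpha_i^{(c)} \ge \alpha_c(x)\} + 1}{n_c + 1},$$

ties counting as greater-or-equal. At significance level $s$ (default 0.8),
class $c$ enters the prediction set iff $p_c > 1 - s$ (strict inequality; a
small epsilon absorbs the floating-point representation of $1-s$). A
singleton set is a definite positive or negative; both-or-neither is
*uncertain*. Per-prediction reliability is summarised as
$\mathrm{significance} = 1 - \min(p_0, p_1)$ and
$\mathrm{confidence} = 100 \cdot \max(p_0, p_1)$ — note $p_0 + p_1 \ne 1$;
these are raw conformal p-values, not posterior probabilities.

Mondrian calibration gives class-conditional validity: among queries whose
true class is $c$, at most a $1-s$ fraction has $c$ excluded from the
prediction set, up to finite-sample noise. The package's test suite checks
this on synthetic exchangeable data (500 training and 500 held-out
molecules, 20% label noise, level 0.8): the observed exclusion rate must
stay under $0.2 + 3\sqrt{0.2 \cdot 0.8 / 500} \approx 0.254$, and accuracy
among definite predictions must reach the level within the same tolerance.
The p-values of the true class are also checked for approximate uniformity
via the Kolmogorov–Smirnov *statistic* (loose bound, $D < 0.2$) rather than
its p-value, because conformal p-values are discrete (calibration-rank
grid) and conservative, which makes the KS p-value itself degenerate.

### Imbalance handling

Two regimes, chosen from the class ratio:

* **Oversampling** (`oversample()`): "doubling the less populated class" is
  implemented literally — each minority record is duplicated exactly once.
  It is deterministic; no SMOTE-style synthesis, no sampling to parity.
* **Balanced-subset ensemble** (`partition_ensemble()` +
  `fit_conformal_ensemble()`): when positives far outnumber negatives,
  subsets are built that each contain *every* negative plus an equal-sized
  sample of positives, with every positive used at least once (shuffle,
  chunk, top up the short chunk by resampling used positives). Member
  predictions combine by majority voting over prediction sets: each model
  adds one vote to every class in its set (a both-classes uncertain votes
  for both, an empty set for neither); strict majority decides, equality is
  uncertain. From bare labels the both/empty distinction is lost, so the
  label-vector convenience path counts `uncertain` as both votes — the
  ensemble predict path keeps the true sets.

The default subset count is `max(3, ceiling(n_pos / n_neg))`.

## Fingerprints and read-across

One structure representation serves the whole pipeline: a 2048-bit hashed
topological path fingerprint (all linear paths of 1–7 bonds over the
canonical structure, plus bare atom paths so single-atom fragments are not
empty; each path key is hashed twice into the bit space with an exact
integer polynomial hash). The dialect string is recorded on every output
(`attr(x, "dialect")`) because fingerprint bits are only comparable within
one dialect. Tanimoto similarity is $|A \cap B| / |A \cup B|$ on the bit
sets; two empty fingerprints are flagged and scored 0 by convention.

Read-across (`rax_infer()`) infers a positive label when the best Tanimoto
similarity to an annotated positive *exceeds* 0.8 (strictly — "higher than
the cutoff"). No negative inference is ever made: a query without a
sufficiently similar positive analogue is reported as `none`, because
non-assessment is not evidence of absence. Nearest-neighbour ties break on
the lexicographically smaller CAS.

## Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `level` | 0.8 | `fit_conformal()` | significance level; guarantees at most `1 - level` errors per class among included labels |
| `calib_frac` | 0.3 | `fit_conformal()` | calibration share of the training data |
| `num_trees` | 500 | `fit_conformal()` | forest size; tuning was deliberately not pursued (quality gains are marginal on these data, and fixed settings keep endpoints comparable) |
| `cutoff` | 0.8 | `rax_infer()` | Tanimoto cutoff, strict inequality |
| `threshold_pct` | 80 | `account()` | high-confidence stratum, inclusive (`>=`) |
| `n` | 10 | `select_validation_set()` | candidates per stratum per class |
| `sparsity` | 0.84 | `generate_source_annotations()` | fraction of uninformed slots in synthetic inventories |

The asymmetry between the strict read-across cutoff (`> 0.8`) and the
inclusive high-confidence rule (`>= 80%`) is intentional: the two rules are
stated differently in the procedure this package operationalises, and both
boundary behaviours are covered by tests.

## Design decisions taken where the design was open

* **Integration tier order.** The precedence (ECHA core -> dossier tier ->
  reference DB -> Pharos, positives beating negatives within a tier) is a
  reconstruction from the prose description of the decision workflow;
  the exact branch diagram is not public. The code→endpoint mapping is
  likewise shipped as an editable CSV (`default_hazard_mapping()`) rather
  than hard-coded, so an auditor can see and change exactly which CLP codes
  feed CMR, etc. ECHA-tier *negative* annotations deliberately contribute
  nothing: those listings assert hazards, not their absence.
* **Curation rule ladder.** The ten categories are named by the source
  methodology but the rules are not; the ladder implemented here (metal
  bond -> salt by fragment count -> organic/inorganic by carbon -> peptide
  by a backbone SMARTS `[NX3][CX4][CX3]=O` counted at least twice) is the
  package's own, each rule an individually testable predicate. Organic
  salts are desalted to the largest organic fragment — the conventional
  choice when salts are declared modelable but no procedure is given.
* **Chemistry toolkit.** Parsing and canonicalisation go through OpenBabel
  (`ChemmineOB`). OpenBabel silently repairs some malformed SMILES and
  accepts hypervalent atoms, so a lexical token-balance check runs before
  parsing and a valence table (charge-adjusted for B/C/N/O; hypervalent
  maxima for P/S/Si/Se and halogens) implements sanitisation. The 2048-bit
  path fingerprint is implemented natively because no installed toolkit
  exposes that representation at bit level.
* **Ranking for validation.** Candidates are ordered by significance first,
  confidence second (configurable): significance reflects the rejected
  class's p-value, the dominant reliability term.
* **Rounding.** All accounting percentages are recomputed from stored
  integer counts and rounded half-up to two decimals; the integers are the
  source of truth. Reference tallies in the wild mix rounding and
  truncation, so comparisons in the acceptance tests allow one unit in the
  last printed digit.
* **Registry multiplicity.** Registries key strictly one-substance-per-CAS;
  inventories where several CAS map to one compound are recorded as
  distinct entries (a known divergence from production databases that merge
  them).

## The synthetic-data generators

`generate_registry()`, `generate_source_annotations()` and
`generate_binary_structure_dataset()` make the whole pipeline testable
offline. They emulate the *statistical* shape of a production inventory:

* CAS-like identifiers with correct check digits;
* a structure mix spanning all ten curation categories, with ~10% of
  substances carrying no structure at all;
* 84% uninformed slots by default, endpoint prevalences chosen to trigger
  each imbalance branch (CMR-like 0.75 -> balanced-subset ensemble,
  PBT/vPvB-like ~0.1 -> oversampling, ED-like 0.985 -> read-across);
* multi-source annotations consistent with a generated ground truth, plus
  an optional conflict rate that integration resolves conservatively;
* for modelling, a binary dataset whose class signal is a structural motif
  (3–5 ring chlorines vs at most one) with labels flipped at a configurable
  noise rate, giving exchangeable data for conformal validity checks.

What they do **not** emulate: real chemical diversity (scaffolds beyond
substituted benzenes and a small template library), any correlation between
a substance's structure and its *annotation* labels in the registry
generator (labels there are drawn independently of SMILES, so an end-to-end
model on registry fixtures will — correctly — abstain on most queries), UVCB
mixtures, or source-specific file formats. Passing tests therefore
demonstrate the correctness of the machinery and the conformal guarantees
under exchangeability, not predictive performance on real inventories.

## Numerical and degenerate-input choices

* Conformal p-value ties count as `>=`, with a `1e-12` slack against
  floating-point jitter in forest probabilities.
* The prediction-set inclusion test adds `1e-9` to `1 - level` so that a
  p-value exactly at the boundary is excluded, as the strict rule requires.
* `tanimoto()` on two empty fingerprints warns and returns 0.
* `extract_training_set()` on an endpoint with an empty class returns an
  explicit unmodelable signal recommending read-across instead of erroring
  mid-pipeline; `rax_infer()` with an empty positive set errors, because
  there is nothing to infer from.
* `evaluate_conformal()` with zero definite predictions reports coverage 0
  and `NA` for the other metrics.
* Problem sizes used by the test suite: the conformal validity check uses
  500 training and 500 query molecules at 20% noise; the remaining tests
  run on datasets of tens to a few hundred records. These sizes keep the
  whole suite around a minute while leaving the Monte-Carlo tolerances
  meaningful.

## Known limitations

* Validity is per endpoint and conditional on exchangeability; distribution
  shift between the annotated substances and the uninformed ones (likely in
  real inventories) erodes the guarantee.
* With very small calibration sets the p-value grid is coarse
  (`1/(n_c + 1)` steps), prediction sets become wide, and most predictions
  are honestly uncertain — visible when triaging small fixture inventories.
* The ensemble's reported p-values are member medians, a ranking heuristic;
  only the voted label carries the conformal interpretation.
* Read-across quality is bounded by the positive set's coverage of
  chemical space; `none` results say nothing about safety.
* The valence table is intentionally permissive for hypervalent-capable
  elements (P, S, halogens), so some exotic but drawable structures pass
  sanitisation.

## A worked example

```{r}
library(toxtriage)

# synthetic inventory
reg_df <- generate_registry(400, seed = 3)
ann <- generate_source_annotations(reg_df, seed = 3)
reg <- registry()
for (i in seq_len(nrow(reg_df))) {
  reg <- register_substance(reg, reg_df$cas[i], reg_df$name[i],
                            reg_df$smiles[i])
}

curation <- curate_registry(reg)
report <- select_modelable(curation)
labels <- integrate_all(reg, ann$annotations)
summarize_registry(reg, labels, ann$annotations)

# a learnable modelling dataset (structural motif + label noise)
train <- generate_binary_structure_dataset(250, 250, noise = 0.2, seed = 101)
model <- fit_conformal(train, level = 0.8, seed = 42)
query <- generate_binary_structure_dataset(250, 250, noise = 0.2, seed = 202)
evaluate_conformal(model, query)
```

The same flow is available from a shell via the thin CLI at
`system.file("cli", "toxtriage", package = "toxtriage")`.
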