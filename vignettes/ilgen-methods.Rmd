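---
title: "Designing low-melting ionic liquids with ilgen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing low-melting ionic liquids with ilgen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Ionic liquids (ILs) are cation–anion pairs whose melting points fall below
roughly 373 K. Their chemical space — every pairing of a plausible organic
cation with a plausible anion — is astronomically larger than the few
thousand ILs that have been characterized, and most of that space has never
been touched. `ilgen` implements a complete computational loop for
exploring it: curate ion corpora, learn what makes an ion "IL-like", use
that signal to steer a generative sequence model, discard chemically
implausible output, and rank candidate pairs by predicted melting point.
This vignette records the models, their assumptions, the defaults, and the
design decisions behind them.

## 1. The pipeline at a glance

1. **Curation** (`filter_general_ions()`, `filter_il_records()`,
   `deduplicate_mpt()`): rule-based cleaning of ion lists and melting-point
   tables.
2. **Ion scorer** (`build_scorer_dataset()`, `select_features()`,
   `train_scorer()`): a soft-label logistic regression that scores an ion's
   resemblance to ions found in known ILs, in `[0, 1]`.
3. **Conditional VAE** (`train_cvae()`, `sample_ions()`): a character-level
   GRU variational autoencoder over SMILES, conditioned on the discretized
   ion score, so that sampling at condition 1 biases generation toward
   IL-like ions.
4. **Post-filter** (`apply_post_filter()`): synthetic-accessibility,
   valence, charge-sign, score and substructure rules that remove
   implausible generated ions.
5. **Melting-point model** (`train_mpt()`, `predict_mpt()`): a regressor
   from pair descriptors to melting point in kelvin, used to rank
   exhaustively combined cation–anion pairs (`combine_ions()`,
   `rank_and_select()`).

Every stage takes and returns tibbles, so the loop composes with ordinary
dplyr pipelines; `run_workflow()` wires the stages end to end.

## 2. Molecular representation

All parsing and canonicalization go through OpenBabel. Parse failures are
data, not errors: `parse_smiles()` returns an `ok` flag per record and
every filter attributes a `parse` rejection rather than aborting a batch.

**Descriptors.** `compute_descriptors()` evaluates a frozen, versioned 1D/2D
descriptor set (`il_descriptor_set()`, id `"ilgen-1"`, 80 descriptors):
physico-chemical estimates (molecular weight, Crippen-type log P, molar
refractivity, TPSA, hydrogen-bond donors/acceptors), whole-graph topology
(ring, branching, Wiener/Zagreb and chain statistics, charge and element
counts), and SMARTS-defined functional-group counts chosen for ionic
chemistry (onium centres, carboxylate/sulfonate/phosphonate heads,
fluorinated motifs, and so on). Fitted models store the descriptor-set id;
a model is only ever applied to the set it was trained on. The exact size
and composition of a "standard" descriptor set varies between toolkits and
versions, which is why the list is frozen in the package rather than taken
from the toolkit at run time.

**Fingerprints.** `compute_ecfp()` is an in-package extended-connectivity
(Morgan) implementation: atom invariants (element, charge, degree, implicit
hydrogens, ring membership) are iteratively rehashed over sorted neighbour
`(bond order, identifier)` pairs and folded into a fixed-width bit vector.
The same fragment identifiers drive the synthetic-accessibility fragment
model, so fingerprints and SA scores see the same substructures. The test
suite cross-checks pairwise Tanimoto orderings against OpenBabel's
independent ECFP4 implementation.

## 3. Synthetic corpora: what they emulate and what they do not

`make_il_like_corpus()` enumerates the classic IL families — imidazolium,
pyridinium, pyrrolidinium, tetraalkylammonium and tetraalkylphosphonium
cations; carboxylate, sulfonate, sulfate-ester, sulfonylimide, phosphonate,
halide and fluoroborate/-phosphate anions — decorated with C1–C8 alkyl and
short functional substituents (about 450 unique cations and 400 anions).
`make_decoy_corpus()` enumerates charged species that chemists would not
expect to form ILs: polyol and amino-acid ammoniums, protonated fused
aromatics, caged amines, multiply charged chains, polyhydroxy and
peptide-like carboxylates, phenolates. Decoys deliberately carry many
hydrogen-bond donors; strong hydrogen bonding raises lattice stability and
melting points, and it is one of the clearest structural separators between
the two populations.

`make_synthetic_mpt_dataset()` assigns melting points from a fully
disclosed generative model:

$$T_m = 450 - 12\,\min(\text{chain}, 8) - 20\,[\text{delocalized anion}]
      + 15\,\mathrm{HBD}_{\text{pair}} + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2),$$

clipped to `[150, 600]` K, with `chain` the longest acyclic sp³ carbon path
of the cation, "delocalized" the sulfonate/sulfonylimide/fluoroborate-type
anion families, and σ defaulting to 10 K. The three terms mimic the real
structure–property folklore (longer chains and charge-delocalized anions
depress melting; hydrogen-bond donors raise it) and make melting-point
modelling a *parameter-recovery* exercise: the tests check that a regressor
recovers a known signal above a known noise floor, not that it reproduces
experimental chemistry. Real melting points carry measurement
irreproducibility (glass transitions, impurities), nonadditive cation–anion
interactions and family-specific quirks that this linear model does not
emulate — passing tests therefore validate the machinery, never accuracy on
laboratory data.

## 4. The ion scorer

Ions from the IL-like corpus are labelled 1, a seeded equal-size sample of
the general corpus 0 (class balance by construction, `|n1 - n0| <= 1`), and
the set is split 80:20 with stratification. Descriptors are z-scored with
training-split statistics. Feature reduction fits an L1-penalized logistic
regression (penalty `lambda = 1/(n C)`, `C = 1` by default — the solver's
conventional default, exposed in the API) on hard labels and keeps the 25
descriptors with the largest absolute coefficients; ranking on standardized
features makes the coefficients comparable across descriptor scales, and
ties break alphabetically so selection is reproducible. Hard labels are
used for selection; smoothing enters only the final fit.

The final model minimizes binary cross-entropy against smoothed targets
`y_ls = (1 - alpha) y + alpha / K` with `alpha = 0.2`, `K = 2`. The labels
are noisy by construction — membership of an ion in an IL database is an
imperfect proxy for "can form an IL" — and smoothing keeps the model from
saturating its probabilities on that imperfect signal. The optimizer is a
fractional-response quasi-binomial GLM: its score equations are identical
to those of the weighted two-row-duplication construction, so either
formulation yields the same fit, and at `alpha = 0` the model coincides
with an ordinary hard-label logistic regression (asserted to `1e-4` in the
tests). Scores at or above the 0.5 threshold classify as IL-like; the
boundary is inclusive-positive, a convention the package documents because
the half-open case is otherwise undefined.

## 5. The conditional VAE

The generator is a character-level sequence VAE. Tokenization is strictly
per character (so `Cl` is two tokens): the vocabulary is the sorted set of
corpus characters plus `PAD`/`BOS`/`EOS`. A regex-style multi-character
tokenizer was considered and rejected as the default to keep the
vocabulary construction rule trivial and corpus-independent.

Architecture (defaults in `cvae_config()`, which are the full-scale
settings: 292-d embeddings and GRU hidden states, three GRU layers, 128-d
latent space, Adam at 1e-4, batch 128, 100 epochs):

* **Encoder.** Each token embedding is concatenated with the condition
  scalar `c` (0/1); a stacked GRU consumes the sequence; the top layer's
  final hidden state maps linearly to the posterior mean and log-variance.
  The posterior is a diagonal Gaussian; training samples it by
  reparameterization, reconstruction uses the mean.
* **Decoder.** `[z || c]` passes through a per-layer tanh linear map to the
  initial hidden states, and `c` is additionally concatenated to every
  decoder input embedding (teacher forcing during training). A linear head
  produces token logits. Where exactly the condition enters the decoder is
  an open wiring choice; injecting it both in the initial state and at
  every step makes the conditioning signal hard to ignore at small scale,
  and the choice is recorded in the model object.
* **Loss.** Per-sequence summed token cross-entropy (PAD masked) plus
  `beta` times the closed-form Gaussian KL to the standard-normal prior.
  `beta` follows a cyclic annealing schedule (4 cycles, linear ramp over
  the first half of each cycle, `beta_max = 1`) — the widely used remedy
  for posterior collapse in sequence VAEs.
* **Decoding.** Multinomial sampling at temperature 1.0 for generation;
  greedy argmax for reconstruction. Reconstruction success is judged by
  canonical-form match, so alternative spellings of the same molecule
  count as correct.

The entire forward/backward pass (full backpropagation through time,
Adam, global-norm gradient clipping at 5) is implemented in plain matrix
algebra and verified against central finite differences to a relative
error below 1e-3 in the test suite — the gradient check, not a framework,
is the correctness authority.

The tests and the reproduction script train a compact variant (48-d
embeddings, one GRU layer, hidden 64, latent 16, learning rate 3e-3, 20
epochs, 800 training ions, maximum length 64); at this scale training
takes about a minute on one CPU, the reconstruction loss decreases
monotonically, sampling validity clears 30% comfortably, and the mean ion
score of condition-1 samples clearly exceeds that of condition-0 samples.
A 20-epoch toy model memorizes sequence syntax long before its latent
space becomes informative (the KL term collapses toward zero), so
reconstruction accuracy at this scale is near chance; the memorization
test (a model trained on a single repeated string reconstructs it exactly)
pins down the mechanism instead.

## 6. Post-filtering

`apply_post_filter()` keeps a candidate iff, in order: it parses; its
synthetic-accessibility score is at most 4; it carries no unpaired
electrons (an atom whose explicit valence cannot be completed to a
standard valence for its element and charge — radicals and carbenes);
its net formal charge has the declared sign; its ion score is at least
0.5; and it matches no unstable-substructure pattern. First failure wins,
so per-rule counts partition the rejected set.

**Synthetic accessibility.** `sa_score()` follows the fragment-contribution
recipe: the mean log-frequency of the molecule's circular fragments in a
reference corpus, minus complexity penalties (size `n^1.005 - n`,
ring-junction atoms, macrocycles), plus a symmetry bonus for repetitive
structures, mapped to the conventional 1 (easy) – 10 (hard) scale. The
fragment table is computed deterministically at load time from a fixed,
code-defined reference corpus of ~160 common organic molecules and stock
ions (weighted toward elementary ionic species, which are ubiquitous
reagents); fragments the corpus has never produced contribute the floor
score −4. Stereocentres are not penalized — stereochemistry is outside the
package's scope. Against the published fragment-based scorer the
implementation agrees in rank order (Spearman > 0.55 on a frozen reference
panel) and, more importantly, in the decisions the 4.0 threshold implies:
common solvents and classic IL ions score 2–3.5, polycyclic cages and
bare reactive anions score above 4.

**Unstable substructures.** The pattern library
(`inst/extdata/unstable_patterns.smarts`, editable, versioned) encodes the
named unstable classes structurally: bare carbanions without an adjacent
stabilizing group, alkoxides on sp³ carbon lacking an α-EWG, N-acyl
quaternary ammonium centres, and adjacent opposite formal charges outside
the legitimate nitro/N-oxide motifs. "Extreme acidity or basicity" is
deliberately handled by these structural classes rather than pKa
prediction; predicted pKa for exotic ions is not reliable enough to gate a
filter.

## 7. The melting-point model

`featurize_pairs()` builds pair features. The default is **per-ion
concatenation**: the frozen descriptor set computed on the cation and on
the anion, as `cation_*` and `anion_*` blocks, with the blocks assigned by
formal-charge sign so the vector is invariant to argument order. The
alternative `mode = "combined"` computes one descriptor vector on the
dot-joined salt. Concatenation is the default for two reasons: it
preserves ion-resolved signals — with combined-salt descriptors the
cation's alkyl-chain length is confounded by anion chains, and on the
synthetic recovery task the held-out RMSE plateaus near 17 K versus about
13.6 K (R² 0.93) for concatenation, against a 10 K noise floor — and it is
the more common convention in IL property modelling. It is also much
cheaper during screening: 100 cations and 100 anions need 200 descriptor
evaluations rather than 10,000.

Backends: `random_forest` (default; 500 trees, toolkit-default `mtry`) and
`xgboost` (500 rounds, depth 6, learning rate 0.1). A
`tabular_foundation` backend name is reserved for transformer-based
tabular models; those require pretrained weights that cannot be bundled,
so requesting it raises an informative error rather than silently
substituting. Training splits 80:20 with a seeded split; RMSE, MAE and R²
are reported on the held-out fifth with the standard definitions.

## 8. Screening

`combine_ions()` forms the exhaustive Cartesian product in deterministic
cation-major order (duplicated inputs are collapsed with a warning — the
product of the unique sets is what "10,000 unique pairs from 100 × 100
ions" means). `rank_and_select()` predicts every pair, sorts ascending and
keeps the requested number, breaking ties lexicographically on the
canonical pair string so ranking is reproducible. Pair identity is the
(canonical cation, canonical anion) tuple; beyond the post-filter's sign
checks no charge-balance constraint is imposed, matching the usual ±1
pairing convention of IL screening.

`project_chemical_space()` embeds structures by Jaccard distances between
their extended-connectivity fingerprints. The default embedding is
principal coordinates analysis: it is deterministic, needs no tuning, and
maps duplicate structures to exactly identical coordinates; seeded
non-metric MDS is available via `method = "nmds"` for a neighbour-faithful
alternative. (A UMAP-style neighbour embedding would serve the same
visualization purpose; PCoA was chosen as the default because it is
dependency-light and exactly reproducible.)

## 9. Numerical and degenerate-input choices

* Curation bounds: molecular weight strictly below 500 Da; charge bounds
  exclusive (anions above −7, cations below +7); log P, donor, acceptor
  and rotatable-bond bounds inclusive. Rule order is fixed and every
  rejection names the first failing rule, so reports are additive.
* Duplicate melting points: a group spread (max − min) beyond 10 K
  discards the whole group; otherwise the mean is used. Max − min is the
  strictest reading that coincides with the two-entry rule.
* The element whitelist defaults to H, B, C, N, O, F, P, Cl, Br, I, Li,
  Na, Al, Si, K, Fe. Sulfur is excluded by default — even though
  sulfonium/sulfonate ions are classic IL chemistry — and admitted with
  `il_elements(include_sulfur = TRUE)`; the synthetic corpora do contain
  sulfur families, so curation with the default list will reject them, by
  design.
* Degenerate model inputs fail loudly and specifically: single-class
  evaluation sets (ROC-AUC undefined), constant truths (R² undefined),
  constant features in a final fit, non-finite CVAE losses, too-long
  sequences (excluded with a logged count).
* All stochastic steps take explicit integer seeds and restore the
  caller's RNG state; two runs with the same seed are bitwise identical.

## 10. Problem sizes used by the tests and the reproduction script

Scorer corpora use 400 ions per class (test split 160); the toy CVAE
trains on 800 ions for 20 epochs and is evaluated on 200 samples per
condition; the melting-point recovery task uses 1,000 pairs at σ = 10 K;
the screening protocol combines 100 × 100 ions and keeps the top 5,000.
These sizes were chosen so that each stage's statistical question (is the
task learnable? does the signal recover? does conditioning separate?) is
answerable in minutes on one CPU; they are study conditions, not tuning
knobs, and the acceptance script re-runs all of them from scratch.

## 11. Known limitations

* The corpora are template-enumerated; they do not emulate the long-tail
  structural diversity of public chemical databases, so scorer and
  generator metrics here say nothing quantitative about performance on
  real corpora.
* The synthetic melting-point law is additive and three-termed; real
  melting behaviour is not.
* The SA fragment table reflects a compact reference corpus: correct
  around common chemistry and IL motifs, but harsher than the published
  table on unusual-yet-makeable scaffolds.
* Radical detection is valence-based; exotic hypervalent species outside
  the supported valence table may be misflagged.
* At toy scale the CVAE's latent space collapses (the conditioning signal,
  not the latent code, carries the structure); full-scale training with
  cyclic annealing is where reconstruction accuracy becomes meaningful.
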