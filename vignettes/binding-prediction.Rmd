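---
title: "Predicting ligand-binding residues from language-model embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ligand-binding residues from language-model embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plmbind` predicts, for every residue of a protein, whether it binds a
metal ion, a nucleic acid (DNA or RNA), or a small molecule. This
vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the synthetic data
generator emulates, and the numerical conventions adopted where several
reasonable choices existed.

## The prediction task

Binding residues are defined structurally: a residue close to a bound
ligand in a solved complex. Curated annotation sets derive per-residue,
per-ligand-class labels from such structures; the conventions mirrored by
the package's annotation reader are

* only X-ray structures at resolution ≤ 2.5 Å are trusted (both are
  reader parameters, `methods_allowed` and `max_resolution` in Å);
* annotations from multiple chains and structures of the same protein
  are merged as a position-wise **union**;
* every residue never observed binding is treated as non-binding;
* peptide ligands are out of scope and skipped with a warning.

The union rule means an observation of binding anywhere wins over its
absence elsewhere; the package follows it strictly, with no
majority-vote alternative. The "not observed = non-binding" convention
systematically understates precision — some "false positives" are simply
unobserved binding — which is one motivation for the reliability index
below.

Labels are multi-label by construction (a residue may bind a metal *and*
a small molecule), stored as an `L × 3` logical matrix in the fixed
channel order METAL, NUCLEIC, SMALL.

## The convolutional sequence labeller

The de novo predictor reads a per-residue protein language model
embedding — an `L × 1024` real matrix, one row per residue — and nothing
else. The architecture is deliberately shallow, reflecting how little
labelled data exists relative to the capacity of modern networks:

```
L × 1024 → conv(k = 5) → L × 128 → ELU → dropout(0.70)
         → conv(k = 5) → L × 3  → sigmoid (per channel)
```

Both convolutions use zero same-padding, so output length always equals
sequence length. The three output channels are **independent sigmoids**,
not a softmax: the truth is multi-label, and a softmax could not
represent a residue binding two classes at once. For the same reason the
training loss is a per-channel binary cross-entropy with a
positive-class weight per channel:

$$\mathcal{L} = -\,\mathrm{mean}_{i,c}\left[\,w_c\, y_{ic} \log p_{ic}
 + (1-y_{ic}) \log (1-p_{ic})\,\right]$$

Default weights are $w = (8.9,\, 7.7,\, 4.4)$ for metal, nucleic and
small molecules. They counter the class imbalance of real annotation
sets, where only about 8% of residues bind anything; heavier weights
push the operating point toward recall, lighter weights toward precision
(a property the test suite checks in direction, not magnitude).

### Training parameters

| parameter | default | why |
|---|---|---|
| optimizer | Adamax | robust per-parameter step scaling; lr 0.01 |
| batch size | 406 proteins | large-batch regime; small sets form a single batch |
| dropout | 0.70 | heavy regularization between the two layers |
| early stopping | patience 10, monitor validation loss | the monitored quantity and patience are the package's choice; the parameters of the best validation epoch are restored |
| validation split | seeded 20% of training proteins, by protein | when no explicit validation set is given |
| decision threshold | 0.5 | a residue is non-binding only when all three probabilities are below it |

Batch membership is assigned by one seeded shuffle at the start of
training and kept fixed across epochs. This lets each batch's im2col
design matrix be built once and cached, and for realistic set sizes
(hundreds of proteins, batch size 406) there are only one or two batches
anyway, so per-epoch reshuffling would change nothing of substance.

Internally a batch is the *concatenation* of its proteins' embedding
matrices. The convolution taps are gathered through an index matrix
whose out-of-sequence entries point at a single virtual zero row — the
exact equivalent of zero-padding each protein separately with the loss
masked at padding, but with no padded compute and no possibility of the
kernel crossing a protein boundary. Inference runs each protein through
its own forward pass, which makes predictions independent of batch
composition down to the last bit.

### Initialization and numerical conventions

* Hidden layer: He-normal (suits the ELU); biases zero.
* Output layer: small random weights (sd 0.01), so the untrained model
  starts at $p \approx 0.5$ everywhere — maximal uncertainty, an initial
  per-channel loss of $\ln 2$ under unit weights, and a reliability
  index of 0. Symmetry is still broken for training.
* The loss is evaluated on log-sigmoid directly (never `log(p)` on a
  saturated probability), so it is finite for any logit.
* All seeded internals (weight init, dropout, splits, bootstrap,
  generators) save and restore the caller's RNG state.

## Reliability index and cutoff sweeps

The probability's distance from 0.5 maps to a single-digit confidence:

$$\mathrm{RI}(p) = \left\lfloor \frac{|p - 0.5| \cdot 9}{0.5} \right\rfloor
 \in \{0, \dots, 9\}$$

0 means $p = 0.5$ (no information) and 9 means $p$ near 0 or 1 —
confident *non-binding* predictions are ranked just like confident
binding ones. The integer rounding rule is a package decision: flooring
keeps the endpoints exact ($\mathrm{RI}(1) = 9$), the map monotone in
$|p - 0.5|$ and symmetric ($\mathrm{RI}(p) = \mathrm{RI}(1-p)$).

`threshold_sweep()` raises the decision cutoff over a grid and reports
**cumulative, residue-pooled** precision and recall over the fixed
protein set plus `CovOneBind`: "the precision of all residues predicted
at probability ≥ c", "the fraction of all annotated binding residues
still recovered". Pooling is deliberate: per-protein averages over a
cutoff-*dependent* protein subset are not monotone in the cutoff
(dropping a protein whose last call was wrong raises the mean), whereas
the pooled cumulative recall and the coverage are non-increasing by
construction — the invariant the test suite asserts. Per-protein
averaged metrics remain the reference mode of `evaluate_predictions()`.

## Homology-based inference

Annotation transfer follows fixed rules:

1. The annotated lookup set is greedily clustered at 95% pairwise
   sequence identity (longest-first, ties by ID) to remove redundancy.
2. The query is aligned locally against every lookup entry; hits must
   reach E ≤ 10⁻³. Self-hits (same identifier) are excluded when
   estimating performance on proteins that are themselves annotated.
3. The hit with the lowest E-value wins; ties break by highest percent
   identity, then lexicographic target ID (a determinism convention).
4. If any binding annotation — of any ligand class — falls on an aligned
   target position, labels are copied between aligned pairs and all
   unaligned query positions become non-binding. Otherwise the hit is
   discarded and no inference is made. Evaluating "any binding in the
   aligned region" across classes rather than per class is a documented
   package choice; a per-class variant would transfer nothing for a
   class whose sites lie outside the alignment even when another class's
   sites lie inside.

The default backend is Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 11 / extend 1) with
a Karlin–Altschul E-value $E = K m n e^{-\lambda S}$ using the standard
gapped parameters for this scoring system ($\lambda = 0.267$,
$K = 0.041$; $m$ = query length, $n$ = total lookup residues). Percent
identity is counted over aligned pairs only (local-alignment
denominator). An `mmseqs2` backend slot wraps the two-iteration
profile-search protocol for large-scale use; it errors explicitly when
the binary is absent — never a silent fallback — because profile
E-values and Smith–Waterman E-values are not interchangeable.

`combine_predictions()` implements the final routing: HBI when a usable
hit exists, the network otherwise. Transferred annotations become hard
pseudo-probabilities (1 at transferred labels, 0 elsewhere), so
HBI-sourced predictions carry RI 9 everywhere and should be excluded
from probability-cutoff analyses; their provenance (hit ID, E-value,
identity) is recorded on the prediction object.

## Evaluation framework

Confusion counts are per protein and per ligand class, with an `ANY`
scope that ORs the three channels on both sides (binding vs.
non-binding regardless of ligand). From `TP, FP, TN, FN` the package
derives recall, precision, F1, MCC, and negative-class recall
(specificity), precision (NPV, `TN/(TN+FN)`) and F1.

Zero denominators make a metric *undefined*, and the resolution policy
is an explicit argument, because both conventions are legitimate and
answer different questions: `"exclude"` drops undefined proteins
(cumulative-curve convention, "among proteins with a prediction…");
`"zero"` scores them 0 (a protein annotated but never predicted to bind
contributes zero precision). There is no silent default beyond the
documented `"exclude"`.

Summaries are per-protein means with symmetric 95% confidence intervals,
either normal ($1.96\,\mathrm{sd}/\sqrt{n}$) or a seeded bootstrap
percentile interval reported as the half-width of its wider side. The
two coverage measures: `CovOneBind` = among proteins annotated for the
assessed scope, the fraction with at least one call (numerator
restricted to the denominator set so the fraction stays in $[0,1]$);
`CovNoBind(l)` = among proteins *not* annotated for class $l$, the
fraction with no call for $l$ (undefined, `NA`, when every protein is
annotated for $l$).

## The synthetic data generator

Real training data for this task — structure-derived annotations paired
with transformer embeddings — cannot ship with a package, so `plmbind`
generates its own study conditions, fully seeded:

* **Embeddings with planted signal.** Background rows are white noise
  (sd 1). Binding residues are planted in short segments (2–5 residues,
  matching the "few key residues" character of binding sites) to an
  overall prevalence of 8%, the imbalance the default loss weights
  address, with ligand classes drawn 20:30:50 (metal:nucleic:small), the
  approximate residue-level mix of large-scale predictions. Each class
  adds a mean shift (default 3) on its own 16 fixed coordinates of the
  1024-wide embedding; neighbours within a ±2 window get a linearly
  attenuated shift, so a k = 5 kernel gains from context the way it
  does on real embeddings. Matrices are full 1024 wide so all real
  shapes are exercised, but the signal lives in a small linear subspace
  a two-layer CNN learns in minutes on one CPU.
* **Homolog families.** A random ancestor carries planted annotation
  segments; members derive from it by seeded point substitutions and
  optional single-residue indels, with the exact ancestor-to-member
  coordinate map retained. Annotations project through the map, so
  transferred labels can be scored against planted truth.

What passing tests on these fixtures show: the trainer optimizes the
intended loss, gradients and optimizer are correct (the planted signal
is recovered far beyond a label-permutation chance baseline, and a
zero-signal dataset collapses to that baseline), and the HBI machinery
transfers labels exactly where the alignment says. What they do *not*
show: performance on real proteins. Real embeddings have rich covariance
structure, binding signal is not linearly separable in a fixed subspace,
and real annotation sets carry the missing-annotation bias discussed
above. The synthetic results validate the machinery, not the biology.

Problem sizes in the test suite are chosen for quick, repeatable runs:
the recovery check trains on the generator's default 200 proteins of
length 50–150 (seed 7), other training tests use 20–60 proteins, and
alignment tests use families of 3–6 members of length 60–200.

## Storage formats

Sequences travel as FASTA; annotations as a flat TSV (`protein_id`,
`ligand_class`, comma-separated 1-based `positions`,
`resolution_angstrom`, `method`); predictions as a per-residue TSV with
probabilities, calls, reliability indices and provenance. Embeddings use
a plain-text store — a directory of one `L × 1024` TSV matrix per
protein, written at full precision (`%.17g`) and read through `strtod`,
so a write/read round trip is bitwise exact. Positions are 1-based and
inclusive throughout, in the protein's own numbering. Model checkpoints
are versioned RDS files holding config, weights and training history.

## Known limitations

* The embedding generator (the language model itself) is out of scope;
  the package consumes pre-computed embeddings through an adapter seam.
* The internal alignment backend's E-values are analytic approximations;
  they order hits correctly but are not interchangeable with
  profile-search E-values from dedicated tools.
* HBI transfers annotations position-wise only; it does not model
  binding-site conservation beyond the alignment.
* Training is CPU-oriented and deliberately small-scale; reproducing
  published large-corpus weights is a non-goal.
* Undefined-metric handling, RI rounding, tie-breaks and the
  across-class discard rule are documented conventions; alternatives
  exist and are flagged above where they would change numbers.
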