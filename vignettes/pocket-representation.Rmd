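---
title: "Distilling ligand similarity into binding-pocket representations"
author: "erepoc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling ligand similarity into binding-pocket representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Binding pockets — the residues surrounding a bound ligand — are the
functional units of protein–ligand recognition, but comparing them is
hard: pockets binding the same ligand can have low 3D structural
similarity, and geometric descriptors miss the physicochemical and
evolutionary context. This package takes a representation-learning view:
it starts from per-residue embeddings of the *whole* protein sequence
produced by a frozen protein language model (1280-dimensional per residue
for the 650M-parameter reference checkpoint), mean-pools the rows
belonging to the pocket residues into one 1280-d feature `P`, and learns
a projection into a 256-d latent space in which cosine similarity between
pockets mirrors the *chemical similarity of their ligands*.

The projection is a two-layer perceptron, 1280 → 512 → 256, each layer
applying an affine map, batch normalization, dropout (rate 0.1) and a
GELU activation. Given a training batch of 128 pocket–ligand pairs, two
similarity structures are built:

* **Q** — the ligand side: pairwise similarities of the 2048-bit radius-2
  circular (Morgan/ECFP4) fingerprints of the bound ligands, cosine by
  default (Tanimoto selectable);
* **P** — the pocket side: pairwise cosine similarities of the projected
  256-d latent vectors.

Each anchor's similarity row over the other 127 batch members is turned
into a probability distribution by a softmax at temperature τ (default
1.0), floored at ε = 10⁻⁸ and renormalized. The loss is the mean
Kullback–Leibler divergence KL(P‖Q) over anchors: training pulls the
learned pocket distribution toward the ligand-similarity target, so
pockets binding chemically similar ligands end up close in latent space.
Optimization uses Adam (learning rate 0.001), early stopping with
patience 100 on the mean validation KL, and at most 2000 epochs of 4096
batches (validation: 256 fixed batches); the checkpoint with the lowest
validation loss is returned.

Three modelling choices deserve a note, because the similarity-to-
distribution step is genuinely open:

* the per-anchor softmax is the standard similarity-distillation
  construction; raw similarities are not probabilities, and the softmax
  makes the KL well defined while preserving the ranking;
* the direction is KL(P‖Q), with the learned distribution in the leading
  position — gradients then weight each pair by the learned probability;
* the ε floor exists purely to guard the logarithm. At batch size 128
  and τ = 1 the softmax probabilities cannot drop anywhere near 10⁻⁸,
  so the floor is inactive in practice, and the analytic gradient
  (verified against central finite differences to better than 10⁻⁴
  relative error in the test suite) treats it as such.

## Pocket extraction and quality control

Two extraction rules are implemented, both operating on heavy atoms
only, so results do not depend on deposited hydrogens:

* **distance rule** — a residue is in the pocket iff any of its heavy
  atoms is within 5 Å (closed boundary, `d ≤ cutoff`) of any heavy
  ligand atom;
* **vdW contact rule** — a residue is in the pocket iff at least two
  (residue atom, ligand atom) pairs sit within the sum of their van der
  Waals radii plus 0.5 Å. The bundled radii are Bondi-style (C 1.70,
  N 1.55, O 1.52, S 1.80, P 1.80, halogens per Bondi); metal ions fall
  back to 2.0 Å. We count distinct atom *pairs*, so one residue atom
  touching two ligand atoms contributes two contacts — the curated
  binding-residue databases do not state this detail either way.

The closed boundary makes the monotonicity property (larger cutoff ⇒
superset pocket) exact. Waters and free metal ions are never treated as
ligands. Alternate conformers keep the highest-occupancy copy.

Transplanted-ligand models are quality-filtered by a steric-clash
report: with clashes defined as heavy-atom pairs closer than 1.2 Å, a
complex is discarded when the intra-pocket clashing pair fraction is
≥ 0.005, the intra-ligand fraction is ≥ 0.01, or the number of
pocket–ligand clashing pairs is ≥ 5; each boundary itself discards.
Fractions are computed over heavy-atom pairs throughout, and a
single-atom group has fraction 0 (it has no pairs).

## Downstream analyses

* **Classification benchmark.** Seven pocket classes named after their
  bound ligand (ADP, COA, FAD, HEM, NAD, NADP, SAM), split 9:1 with
  stratification (which guarantees every class reaches the test set —
  the plain 9:1 ratio is kept per class). Two classifier families run on
  either the raw pooled embeddings or the latent vectors: a feedforward
  net (one hidden layer of 128 GELU units, softmax cross-entropy, Adam
  lr 0.001, 200 full-batch epochs — a fixed deterministic contract) and
  an RBF-kernel SVM (default bandwidth heuristic, one-vs-rest).
  Precision, recall and F1 are computed per class from the confusion
  matrix; zero denominators yield 0 (logged) so macro averages stay
  defined.
* **Similarity search and screening.** Exhaustive (exact) cosine k-NN
  with lexicographic tie-breaks; a strict `> 0.8` threshold for
  "neighbour" calls; proteome screening keeps pockets with volume
  ≥ 800 Å³ (the boundary keeps), mean pocket pLDDT ≥ 0.7 (both 0–1 and
  0–100 input scales accepted and normalized) and maximum cosine to the
  reference panel strictly above 0.8, deduplicated per accession by
  maximal cosine.
* **Class enrichment.** The enrichment score of class *i* is the
  proportion of class-*i* proteins among hits over its background
  proportion, and significance is the one-sided upper-tail
  hypergeometric probability P(X ≥ observed). The printed point-mass
  form of the probability is available as a debug mode, but a point mass
  is not a test for over-representation, so the tail is the default.
  Multifunctional proteins count in every annotated class, while the
  background total counts proteins once. No multiple-testing adjustment
  is applied by default (a Benjamini–Hochberg column is optional).
* **Docking-score statistics.** Z-scores standardize by the *global*
  mean and standard deviation over all compounds (population sd — the
  sample/population choice is configurable and not stated by the
  conventions this follows); the enrichment factor at cutoff *c*
  compares the fractions of the two pools scoring ≤ *c*, undefined (and
  reported missing, never infinite) when the comparison pool is empty at
  *c*; the Monte Carlo EF curve resamples 200 compounds per pool over
  1000 iterations without replacement and reports mean ± sd per cutoff;
  "top 1%" means the ⌈0.01·n⌉ most negative scores per target with ties
  broken by compound id; and the one-sided Mann–Whitney U test (x
  stochastically smaller) uses midrank ties with exact enumeration up to
  a combined n of 20 and the tie-corrected, continuity-corrected normal
  approximation beyond, with effect size r = z/√N.

## What the synthetic fixtures emulate

The package is fully testable offline because every input is generated
by code:

* **Toy structures** place three-atom residues at controlled distances
  from a small ligand cluster, so pocket membership and planted 1.0 Å
  clash pairs are known analytically from the generating coordinates.
* **The embedding dataset** mirrors the seven-ligand benchmark's
  statistical shape: 7 classes × 200 pockets, dimension 1280. Class
  centers are drawn N(0, 1) per coordinate and samples add N(0, 1.5²)
  noise, giving a raw within-class cosine around 0.3 — deliberately
  weak separation, emulating how raw pooled language-model embeddings
  only partially separate pocket types. Fingerprint templates use 48
  class-specific bits plus 16 bits shared across classes, with
  independent bit flips at rate 0.005 (chosen for analytic tractability
  of the expected Tanimoto); the realized within/between similarity gap
  (≈ 0.6) is reported in the metadata and asserted > 0.2.
* **Docking pools** are Normal(μ₀, σ) vs Normal(μ₀ − 1.5σ, σ) with
  μ₀ = −6 kcal/mol, σ = 1 — a clean two-group location shift whose
  enrichment factor has the closed form Φ((c−μ₀+Δ)/σ)/Φ((c−μ₀)/σ).

What passing on these fixtures shows is that the machinery is correct
and that the contrastive objective can recover planted
similarity structure; it says nothing about real protein biology —
the synthetic provider has no evolutionary information, Gaussian
clusters are far cleaner than real embedding geometry, and fingerprint
templates are far cleaner than real chemotypes.

## Problem sizes and numerical choices

The test suite and the acceptance script train the full 1280→512→256
architecture on the 1400-pocket fixture with a scaled-down schedule:
64 training batches per epoch, 16 validation batches, patience 10, at
most 100 epochs. These sizes were chosen so a complete run is a
few minutes on one CPU core while still exercising the exact tensor
shapes of the reference recipe; with the default schedule (4096
batches/epoch, patience 100) the same code handles database-scale
training, just not inside a test run. Validation batches are drawn once
at startup (resampling them each epoch would add noise to the early
stopping signal); training batches are drawn with replacement from the
training pool; the train/validation split is 90/10 by pocket, seeded.

Two further numerical notes:

* Batch normalization uses batch statistics (population variance) in
  training and running statistics in eval mode (momentum 0.1, unbiased
  variance feeding the running estimate), so encoding is deterministic
  and batch-order invariant — the tests assert bit-equality under
  permutation.
* The Monte Carlo EF mean is compared against the full-pool EF at
  *interior* cutoffs. At deep-tail cutoffs the per-iteration EF is a
  ratio of small binomial counts and is biased upward (a Jensen effect
  of order 1/E[count]); this is a property of subsampled EF estimates in
  general, visible in the reported per-cutoff standard deviations, not a
  defect of the estimator. The curve still reports those cutoffs, with
  the number of defined iterations.

## Known limitations

* Generalization to ligand classes held out of training (the
  `ablationHoldout()` harness) is weak *on the synthetic fixture*: the
  trained projection concentrates pockets in a narrow GELU-positive
  cone and attenuates embedding directions it never needed, and because
  the fixture's class centers are isotropic random directions, there is
  no shared structure along which an unseen class could be preserved —
  held-out classes end up with only a small within-versus-cross cosine
  margin. This is a consequence of the fixture's deliberately minimal
  geometry (see above), not of the optimization; with real
  language-model embeddings, whose classes share physicochemical
  structure, held-out behaviour must be assessed on real data.
* The pretrained language-model provider is an interface contract here;
  offline use runs the synthetic provider, and real embeddings must be
  computed externally (or the checkpoint supplied) before the learned
  projection is scientifically meaningful.
* Multi-chain pockets are pooled across all mapped residues regardless
  of chain; whether pooling should be chain-restricted is an open
  convention and may matter for oligomeric interfaces.
* The 5-NN search excludes only exact pocket-id self-matches; pockets of
  the same protein deposited twice count as neighbours.
* Fingerprints come from RDKit via the system Python; an R session
  without that interpreter can read/write fingerprint TSVs and run every
  downstream step, but cannot compute new fingerprints from SMILES.
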