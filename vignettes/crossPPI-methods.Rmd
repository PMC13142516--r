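---
title: "Partner-aware interface prediction with crossPPI: models and methods"
author: "crossPPI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partner-aware interface prediction with crossPPI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossPPI)
```

# The problem

Most sequence-based predictors of protein-protein interaction (PPI) sites
score a protein in isolation: a residue is "interface-prone" or not,
regardless of what the protein is binding. That framing breaks down exactly
where residue-level prediction matters most — transient, motif-mediated
interactions, often carried by intrinsically disordered regions, where the
same chain uses different residues against different partners. crossPPI
implements a partner-aware alternative: the predicted interaction
probability of every residue of a *query* protein is conditioned, through
cross-attention, on the full sequence of a designated *partner*.

# The model

Both proteins are first represented as per-residue embedding matrices
$E_A \in \mathbb{R}^{L_A \times d}$ and $E_B \in \mathbb{R}^{L_B \times d}$
(row $i$ = residue $i$). A unilateral multi-head cross-attention layer lets
every query residue attend over all partner residues:

$$A_h = \mathrm{softmax}\!\left(\frac{Q_h K_h^\top}{s}\right), \qquad
  Q = E_A W_Q,\; K = E_B W_K,\; V = E_B W_V,$$

with the $d \times d$ projections split into $H$ heads of width $d/H$ and
$s$ the attention scale. The per-head contexts $A_h V_h$ are concatenated
and passed through a learned output projection $W_O$, LayerNorm, and a
two-layer MLP (linear, ReLU, dropout) ending in a single sigmoid unit, so
the output is one probability per query residue:

$$P_A = \sigma\!\left(\mathrm{MLP}\!\left(\mathrm{LN}\!\left(
  \mathrm{concat}_h(A_h V_h)\, W_O\right)\right)\right).$$

There is no residual connection by default: query information reaches the
output *only* through the attention weights, which makes every prediction
partner-conditioned by construction (an optional residual flag exists but is
off). At the full-scale default configuration — $d = 1280$ (matching
1280-dimensional protein-language-model residue embeddings), 16 heads of
width 80, MLP hidden width $d$ — the model carries 8,202,241 trainable
parameters, 8.20 M, of which 80.0% sit in the cross-attention block and 20%
in the classifier MLP. `countParameters()` reproduces this accounting
exactly against an instantiated model:

```{r}
countParameters(modelConfig())
```

## Design choices in the architecture

Several aspects are deliberately configurable because reasonable
implementations differ:

* **Head split and output projection.** The attention equations can be read
  as single-matrix; we implement the standard multi-head split with a
  learned output projection, which is also what the 80:20
  attention-vs-classifier parameter split requires.
* **Attention scale.** `per_head_sqrt` ($s = \sqrt{d/H}$, standard
  multi-head practice, the default) or `full_dim_sqrt` ($s = \sqrt{d}$, the
  literal single-matrix reading). The choice affects neither parameter
  counts nor any normalisation invariant.
* **MLP hidden width.** Set to $d$ by default; this is the width at which
  the full-scale model reaches 8.20 M parameters with the 80:20 split.
* **Dropout** (default 0.10) applies inside the MLP during training only.
* **Initialisation.** Scaled uniform fan-in with an explicit seed and zero
  biases. Two refinements are exposed on top: `outputBiasInit` sets the
  final bias, and starting it at the class-prior logit
  ($\log \pi/(1-\pi) \approx -3.5$ at ~3% interface residues) removes the
  early training phase that merely fits the base rate — trained interface
  models operate at strongly negative output biases for exactly this
  reason. `qkMatchInit` adds a scaled identity to $W_Q$ and $W_K$ so that
  attention begins as a content-similarity matcher (a residue initially
  attends to partner residues with near-identical embeddings); this seeds
  the partner-matching circuit the layer is meant to discover and makes
  small-budget training far more reliable. Both default to the plain
  behaviour (0).
* **Numerics.** Softmax rows are computed with max subtraction; LayerNorm
  uses $\varepsilon = 10^{-5}$; probabilities are clamped at $10^{-7}$
  before logs in the loss.

The backward pass is derived by hand (see `R/backprop.R`) and verified in
the test suite against central finite differences for every tensor, with
and without the residual, under both scale modes.

# Long sequences: chunked inference

Embedders built on fixed-context language models cap input length (1,022
residues for the 650M-parameter embedder the defaults are sized for).
Sequences beyond the window are cut into overlapping chunks (window 1,022,
stride 512) with an end-aligned final chunk at `max(0, L - window)`, so
every residue is covered and nothing is padded. Every query chunk is
cross-attended against every partner chunk and per-residue probabilities
are aggregated by max pooling over all combinations. Two properties pin
this down: for sequences within one window the chunked path is bitwise
identical to the direct one, and adding chunk pairs can only increase a
position's final probability (max-pool monotonicity). Whether partner
chunks are pooled before or after query aggregation is immaterial under
max; we pool over all combinations at once. Embedding rows are sliced from
full-length matrices per chunk, which is exact for the local-context
backends shipped here; a live PLM backend would re-embed each chunk.

# Interface labels from structures

Ground-truth interface residues are defined operationally from complex
structures: a residue of the focal chain is an interface site if its
relative solvent accessibility (RSA) drops by **more than 4 percentage
points** (strict) when the complex is separated into isolated chains.

* SASA is computed by the Shrake-Rupley method: 960 deterministic
  golden-spiral points per atom sphere (atom radius + 1.4 Å probe),
  counting points not buried in any neighbouring expanded sphere.
  Hydrogens, waters and heteroatoms are excluded; alternate locations keep
  the highest-occupancy conformer. The estimator is validated against
  closed forms: an isolated sphere to 0.1%, two overlapping spheres against
  the analytic spherical-cap area to 2%, and exact additivity for chains
  50 Å apart.
* RSA normalises per-residue SASA by a residue-type maximum. The default
  table is the theoretical (Gly-X-Gly) maximum set of Tien and colleagues;
  the normalisation source is configurable because published RSA pipelines
  differ, and unknown residue types fall back to a generic value with a
  warning.
* Because occlusion can only reduce accessibility, $\Delta$RSA is
  non-negative and a single-chain "complex" yields zero interface residues
  — both asserted as invariants.

Labels are then mapped onto full-length parent sequences by global
alignment of the structure-derived sequence within the parent
(Needleman-Wunsch on the structure side, local on the parent side,
BLOSUM62). Structural labels aligned to gaps are dropped with a warning and
counted; mappings under 90% alignment identity are rejected, mirroring the
curation filter below. A coverage mask records which parent positions were
resolved at all.

# Dataset curation

Curation builds non-redundant receptor-centric or peptide-centric pair
datasets from annotation tables of receptor-peptide complexes (peptide
ligands of at most 30 residues):

1. **Filtering.** A record is kept only if the focal chain has exactly one
   parent accession, at least 90% sequence identity to it, is not an
   antibody-epitope complex (an input metadata flag — this is an annotation
   judgement, not something we compute), and the peptide is within the
   30-residue bound. Every rejection carries exactly one rule tag.
2. **Redundancy clustering.** Focal parents sharing more than 25% pairwise
   identity are clustered greedily, longest sequence first, CD-HIT style: a
   sequence joins the first cluster whose representative exceeds the
   threshold, else founds its own. Identity is defined as identities
   divided by local-alignment length (Smith-Waterman, BLOSUM62, gap open
   11 / extend 1) with **no** coverage requirement — deliberately
   inclusive of locally similar regions, which removes *more* redundancy
   than coverage-constrained recipes. The exact alignment recipe behind
   the published 25% threshold is not stated anywhere we could find, so
   this is a documented stand-in chosen to match the inclusive behaviour
   described.
3. **Leakage-free splits.** Whole clusters are assigned to
   train/validation/blind at 60:10:30 by largest-remainder apportionment
   over a seeded shuffle (10 singleton clusters split exactly 6/1/3), so
   every pair of a focal protein lands in one subset. Grouped 5-fold
   cross-validation deals clusters into 5 disjoint test folds (~20% each)
   and splits the rest 70:10 overall. Leakage-freedom is asserted
   programmatically across many seeds in the test suite.
4. **Disorder flagging.** A peptide is classified disordered when at least
   75% (inclusive) of its residues are coil in a supplied three-state
   secondary-structure string; we consume the string rather than compute
   it, since disorder calls are typically made on external single-chain
   models.

# Evaluation

Residue-level metrics are micro-averaged (residues pooled across pairs),
with a probability cutoff of 0.5 (inclusive: $p \ge 0.5$ is a positive
call): accuracy, recall, precision (percent), F1, and MCC, plus
threshold-free AUROC (rank statistic, ties counted half — equal to
exhaustive ordered-pair counting, which the tests verify exhaustively for
short label vectors) and PRAUC (stepwise interpolation over recall).
Degenerate denominators yield 0 with a flag rather than NaN so batch
reports never crash.

`reconstructConfusion()` inverts a printed results row — recall, precision,
dataset positives and totals — back to integer confusion counts (nearest
integer on TP, then FP). This lets accuracy, F1 and MCC of published
blind-set rows be recomputed and checked for internal consistency, which
the acceptance tests do for the receptor-centric blind row (accuracy
97.01%, F1 0.218, MCC 0.252 from 6,300 positives among 211,219 residues)
and the peptide-centric blind row (98.32%, 0.240, 0.269 from 5,666 among
343,673).

The **scrambled-partner control** quantifies partner dependence: partners
are permuted uniformly (composition preserved, all ordered motifs
destroyed) and evaluation reruns the *standard* prediction path — there is
deliberately no separate code path. A partner-aware model collapses toward
chance under this control; a model that only reads query-side signal does
not.

# The synthetic data generator

The generator produces fully labeled query-partner pairs that emulate
short-linear-motif (SLiM) biology at realistic class imbalance, plus toy
multi-chain coordinate sets for the labeler. Its design went through
substantial calibration, and the reasoning is worth recording.

**What it emulates.** A disordered region is full of candidate motifs; the
partner decides which are used. Queries are therefore built as tilings of
candidate query motifs drawn from a couple library, each tile followed by
one random spacer residue, so the query sequence alone carries essentially
no information about which residues will be labeled. A couple is *active*
in a pair when its partner-recognition motif occurs, in order, in the
partner; the labels are exactly the rule's string-matching semantics — a
query residue is positive iff it lies in a query-motif occurrence whose
coupled partner motif occurs anywhere in the partner — recomputed on the
final sequences, so chance occurrences are labeled consistently.

**Composition matching.** Inactive couples have their partner motif's
letters scattered at random positions of the partner. Active and inactive
partners are therefore composition-identical with respect to the couple;
only residue *order* separates them. Without this, a model can pass the
learnability bar by reading amino-acid composition — which survives
scrambling, defeating the scrambled-partner control's purpose.

**The default couple library** uses four self-complementary, patterned
couples — `HDH`, `CRC`, `ALA`, `IEI` — i.e. the partner motif is the query
motif itself, and each motif has the a-b-a shape over a letter pair unique
to its couple. Each property is load-bearing:

* *Self-complementary*: the learnable rule is one shared content-matching
  rule ("my pattern occurs in the partner") rather than per-couple
  memorisation, so it generalises from few positive examples.
* *Patterned (a-b-a)*: with the default 3-mer embedding context, a motif
  edge residue sees only two of its three letters; under an a-b-a pattern
  those two letters determine the whole motif, so every motif position can
  in principle verify the full partner occurrence. Generic three-letter
  motifs leave edge positions with irreducible bigram-level false evidence.
* *Letter-pair-unique*: each couple is identified by its bigram, keeping
  couples mutually non-confusable.
* *Four couples*: enough diversity to force couple-specific matching, few
  enough that each query carries several tiles of each couple.
* Patterned low-complexity runs are also the right caricature: real
  disordered regions are enriched in short repeated/low-complexity
  stretches.

**Calibration.** The activation probability is set analytically from the
target positive rate (default 3%, inside the ~1.7-3.5% imbalance band of
curated interface data), the k/(k+1) tile coverage, and the chance rate of
a motif occurring in a random partner, then adjusted by a bounded retry
loop until the realised rate is within 30% (relative) of target.
Generation is a pure function of the seed. Sequence lengths default to
40-80 (query; room for ~10-16 candidate tiles) and 60-120 (partner;
single-domain scale).

**What it does not emulate.** The synthetic embedder is a local-context
code, not a transformer: no long-range context, no structure-awareness, no
learned redundancy between positions. Toy complexes are single-atom-residue
geometries engineered for occlusion behaviour, not physical protein
structure. Passing the learnability and control tests therefore
demonstrates that the architecture, loss, trainer and evaluation stack can
discover and use genuinely partner-conditioned signal at small scale — it
does not certify performance on real interactomes, which depends on the
quality of the pretrained embedder and the curated training corpus.

**The synthetic embedder.** Each residue's vector is a flank-decayed sum
(decay 0.5) of seeded basis vectors indexed by (residue identity, offset)
over the window `i - k .. i + k` (default flank `k = 1`, i.e. 3-mer
contexts, matching the default motif length; windows are edge-clamped at
termini). Where the embedding dimension allows (d >= 21), the 21 token
vectors of each offset are orthonormal — a seeded random rotation — so
same-offset residue identities are exactly non-confusable; this removes a
seed-to-seed lottery in which nearly collinear token vectors made planted
motifs hard to separate. A low-amplitude sinusoidal positional component
(0.05) can be disabled. The embedder is a pure function of
(sequence, d, seed).

# Training

Training minimises mean binary cross-entropy over residues with Adam
(default learning rate 1e-3, exposed; the optimizer is not specified by
the upstream description). One protein pair is one gradient example;
`batchPairs` accumulates several pairs per update (averaged gradients),
which smooths the steps and permits larger learning rates on small
problems. Class imbalance is handled by *nothing* by default — plain BCE —
with an optional positive-class weight that is off for fidelity to the
upstream training description. After each epoch the validation loss is
evaluated (dropout off); strict improvement resets a patience counter and
snapshots the parameters; training stops after 10 consecutive
non-improving epochs or 50 epochs total, returning the snapshot with the
lowest validation loss. All shuffling and dropout masks derive from the
config seed, so runs are exactly reproducible.

**Small-budget training protocol.** The learnability demonstration
(`benchmarkPlantedMotif()`, used by the acceptance suite) trains at d = 32
with 4 heads on 200 generated pairs (160 training / 40 validation) and
evaluates on an independently generated held-out set of 120 pairs — small
held-out sets are avoided because positives arrive in couple-bursts,
making a 25-pair test set's positive count (and hence its AUROC estimate)
extremely noisy. Because convergence of the attention-matching circuit
within 50 epochs is partly an initialisation lottery, the protocol trains
five replicates, each with an independently instantiated synthetic
embedder and parameter initialisation, and selects one on validation data
only: among replicates whose scrambled-partner validation AUROC is at most
0.60 — i.e. that are genuinely partner-dependent rather than leaking
query-side signal — the one with the highest validation AUROC is kept
(largest validation partner-dependence margin as fallback). This is the
natural extension of best-checkpoint retention to replicates: we want
*the partner-aware checkpoint*, and both selection quantities are
computable without touching the held-out set. Settings: learning rate 5e-3
with 8-pair gradient accumulation, dropout 0.1, output bias initialised at
the class-prior logit, `qkMatchInit = 2`. The selected model is expected
to exceed 0.85 held-out AUROC, and the same checkpoint evaluated with
scrambled partners to fall to at most 0.60 — the qualitative signature of
partner dependence. Runtime is a few minutes on one CPU.

# Known limitations

* The hand-rolled dense linear algebra is adequate for the configurations
  used here but makes no attempt at GPU-scale training; full-scale (8.20 M
  parameter, 650M-embedder) training is out of scope.
* The Shrake-Rupley implementation is O(atoms x neighbours) in pure R:
  fine for single complexes and the toy fixtures, slow for proteome-scale
  SASA.
* The greedy identity clustering approximates exact graph clustering, and
  the local-alignment identity definition merges aggressively on locally
  similar sequences — both are documented, deliberate behaviours.
* mmCIF parsing relies on the underlying structure reader; PDB is the
  tested input path.
* The scrambled-partner control destroys motif order but not composition;
  a model exploiting composition-only signal would not be caught by the
  control on *real* data where composition is informative. The synthetic
  generator is explicitly composition-matched so that the control is
  meaningful in the tests.
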