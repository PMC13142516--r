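# crossPPI

Partner-aware prediction of protein-protein interaction (PPI) sites in R.

Most sequence-based interface predictors score a protein in isolation.
crossPPI conditions every prediction on a specific binding partner: a
multi-head **cross-attention** layer lets each residue of a query protein
attend over all residues of a partner sequence, and the attended,
partner-conditioned representation is classified into a per-residue
interaction probability. The package is aimed at computational biologists
studying transient, motif-mediated and disorder-mediated interactions,
where the interface depends on *which* partner is bound.

For embeddings $E_A \in \mathbb{R}^{L_A \times d}$ and
$E_B \in \mathbb{R}^{L_B \times d}$ of a query A and partner B:

    A_h = softmax(Q_h K_h' / s),  Q = E_A W_Q,  K = E_B W_K,  V = E_B W_V
    P_A = sigmoid(MLP(LayerNorm(concat_h(A_h V_h) W_O)))

At the full-scale default configuration (d = 1280, 16 heads, MLP hidden
width d) the model carries 8,202,241 trainable parameters — 8.20 M, with
80% of capacity in the cross-attention block.

Around the model, the package ships the full supporting stack:

* **Embedding backends** — a deterministic synthetic local-context
  embedder for testing, a file loader (JSON header + binary matrix), and
  an adapter contract for pretrained protein language models;
* **Chunked inference** — overlapping 1,022-residue windows with stride
  512 and max-pool aggregation for sequences beyond the embedder context;
* **Training** — hand-derived backpropagation, Adam with optional
  gradient accumulation, early stopping (patience 10, max 50 epochs) with
  best-checkpoint retention;
* **Interface labeling** — Shrake-Rupley solvent-accessible surface area
  and the Delta-RSA > 4% complex-separation criterion, mapped onto
  full-length parent sequences by alignment;
* **Dataset curation** — annotation filtering, greedy 25%-identity
  clustering of focal proteins, leakage-free 60:10:30 and grouped 5-fold
  70:10:20 splits, coil-fraction disorder flagging;
* **Evaluation** — micro-averaged residue-level metrics (accuracy,
  recall, precision, F1, MCC, AUROC, PRAUC), reconstruction of confusion
  counts from printed results rows, and the scrambled-partner control;
* **Synthetic data** — paired sequences with planted partner-conditioned
  interface motifs at realistic (~3%) class imbalance, and toy
  multi-chain coordinate sets for the labeler;
* **A command-line wrapper** (`exec/crossppi`) with subcommands
  `predict`, `train`, `label`, `curate`, `evaluate`, `scan`, `simulate`.

## Worked example

Train a small partner-aware model on synthetic planted-motif data and
check that it (a) finds the planted interfaces of unseen pairs and (b)
collapses when the partner is scrambled. `benchmarkPlantedMotif()` wraps
the whole study — data generation at ~3% interface residues, five training
replicates with early stopping, replicate selection on validation data,
and evaluation on an independent held-out set:

```r
library(crossPPI)

bench <- benchmarkPlantedMotif(seed = 1)
round(c(heldout_auroc   = bench$heldoutAuroc,
        scrambled_auroc = bench$scrambledAuroc,
        positive_rate   = bench$realizedPositiveRate), 3)
#>   heldout_auroc scrambled_auroc   positive_rate
#>           0.901           0.539           0.026
```

A held-out AUROC of ~0.90 that falls to ~0.54 under scrambled partners is
the signature of genuinely partner-conditioned prediction: permuting the
partner preserves its composition but destroys the ordered motifs the
attention layer matches, so the ranking collapses toward chance. The
underlying pieces (`generatePairDataset()`, `embedSequence()`,
`initModel()`, `trainModel()`, `predictPair()`, `scramblePartner()`,
`auroc()`) are all exported and composable.

Parameter accounting at full scale:

```r
countParameters(modelConfig())
#> attention_block       mlp_block           total
#>         6561280         1640961         8202241
```

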