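---
title: "Contrastive alignment of two single-cell modalities: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive alignment of two single-cell modalities: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Paired single-cell multi-omics assays (SHARE-seq, 10x Multiome, CITE-seq)
measure two molecular layers — say gene expression and chromatin
accessibility — in the same physical cells, but the two measurements live in
completely different feature spaces with different distributions, sparsity
and noise. Unpaired designs are even harder: each cell is observed in only
one modality, and only a shared cell-type vocabulary links the two
populations. `modalign` learns a single latent space in which a cell's two
modality profiles (or, for unpaired data, cells of the same type across
modalities) sit close together, so that cross-modal retrieval, label
transfer and joint visualization become ordinary nearest-neighbor
operations.

## The model

Let $x_i \in \mathbb{R}^p$ and $y_i \in \mathbb{R}^q$ be a cell's
(preprocessed) profiles in the two modalities. Two encoders
$f: \mathbb{R}^p \to \mathbb{R}^d$ and $g: \mathbb{R}^q \to \mathbb{R}^d$
share one architecture: a linear map to a hidden layer (default width 256),
batch normalization, ReLU, a second linear map to the latent dimension
(default $d = 128$), and row-wise L2 normalization so embeddings lie on the
unit sphere and inner products are cosine similarities. We place the
nonlinearity between the two linear maps: a ReLU *after* the final layer
would confine all embeddings to the nonnegative orthant, collapsing the
usable range of cosine similarity.

Training uses mini-batches structured by cell type. A batch contains $M$
cells per modality, one cell from each of $M$ distinct cell types, and the
$M \times M$ similarity matrix $S_{ij} = f(x_i)^\top g(y_j)$ is formed. The
diagonal holds the positive pairs — the same cell in both modalities when
data are paired, or two same-type cells (one per modality) when unpaired —
while every off-diagonal entry is a cross-type negative. The per-anchor loss
is the symmetric softmax cross-entropy on the diagonal,

$$
L(i) = -\tfrac{1}{2}\,
  \ln\frac{e^{S_{ii}}}{\sum_j e^{S_{ij}}}
  \;-\; \tfrac{1}{2}\,
  \ln\frac{e^{S_{ii}}}{\sum_j e^{S_{ji}}},
$$

summed over the $M$ anchors of the batch. The row half retrieves modality 2
from modality 1 and the column half the reverse; the total is invariant
under swapping the modalities (transposing $S$). There is no temperature
parameter in the base form; an optional one (default 1, i.e. off) is
exposed for experimentation. Because same-type cross-modal pairs other than
the chosen positive never appear inside a batch (types are distinct within
a batch), a pair of distinct same-type cells is *neither* positive nor
negative — the construction sidesteps the false-negative problem that a
purely random mini-batch would create.

Both encoders are optimized jointly with Adam (learning rate $10^{-3}$ by
default, configurable — the optimizer is not dictated by the loss and this
is the standard choice for contrastive objectives). Training runs up to 150
epochs with early stopping on the epoch-mean training loss: patience 10
epochs, minimum improvement $10^{-4}$ relative to the best loss so far. No
validation split is carved out for the stopping rule; the monitored
quantity is the training loss itself, which keeps the full training set
available to the encoders.

### Mini-batch scheduling

One epoch contains as many batches as the largest per-type cell count.
Within an epoch each type's cells are consumed in shuffled order without
replacement; rarer types are topped up by sampling with replacement so
every batch keeps the strict one-cell-per-type structure the loss requires,
and every training cell appears at least once per epoch. $M$ defaults to
the number of (shared) cell types; beyond a cap of 512 types, batches
subsample types with a warning. In the unpaired case the two modality draws
are independent, and types present in only one modality are excluded with a
warning.

## Preprocessing

The chain is the standard UMI pipeline, in fixed order: per-cell
total-count normalization (target sum $10^4$, the counts-per-10k
convention), $\log(1+x)$, per-feature scaling to zero mean and unit
variance, and PCA to (default) 100 components per modality. Provider-
preprocessed inputs such as normalized CITE-seq matrices can skip the two
count-specific steps via `preprocess_config(normalize = FALSE, log1p =
FALSE)`. Three numerical choices matter:

* **Population variance** (divide-by-$n$) in scaling — deterministic and in
  line with common single-cell scaling implementations; zero-variance
  features are centered and passed through with a unit divisor rather than
  producing NaN.
* **PCA via SVD of the centered matrix**, component signs fixed so each
  axis's largest-magnitude loading is positive — byte-reproducible across
  platforms.
* **`n_pcs` is capped at `min(n_cells, n_features)`** with a message, so
  small subsets (e.g. the minor modality at a 5% unpairing proportion)
  remain processable.

Every statistic is fitted on the training rows of a replicate only
(`fit_preprocess()` records `fitted_on` for audit) and applied frozen to
held-out cells; `embed_holdout()` runs the encoders in evaluation mode with
batch-norm running averages, so a single cell embeds deterministically and
independently of its companions.

## Evaluation protocol and metrics

Evaluation uses replicated train/test splits (default 10 replicates,
hold-out fraction 0.3 — the protocol fixes the replication, and 30% is the
common hold-out convention; replicate $r$ uses seed $\texttt{base} + r$).
Training never receives test rows; the acceptance suite verifies that
replacing the entire hold-out set with garbage changes neither the fitted
preprocessing statistics nor a single trained weight.

Five metrics are computed on hold-out embeddings, in both retrieval
directions where applicable:

* **Recall@k** — fraction of cells whose matched counterpart is among their
  $k$ nearest cross-modal neighbors (Euclidean). Requires a paired
  hold-out; chance level is $k/N$.
* **Cell type@k** — mean fraction of a cell's $k$ cross-modal neighbors
  sharing its type; applicable to unpaired hold-outs.
* **Cell type accuracy** — cell type@k at $k = 1$ (identically).
* **Median rank** — median, over cells, of the matched counterpart's rank
  among all $N$ cross-modal distances; reported raw and normalized as
  $\mathrm{raw}/N$ (the normalization denominator is our choice; it sends
  perfect alignment to $1/N \approx 0$). The matched pair receives the best
  rank among distance ties (optimistic rule); k-nearest-neighbor ties are
  broken by reference index, deterministically.
* **Normalized ASW** — mean silhouette width over cells of the joint
  embedding with cell-type labels as clusters and Euclidean distance,
  mapped to $[0,1]$ via $(\mathrm{ASW}+1)/2$. The joint embedding
  concatenates the two $d$-dimensional embeddings per cell ($N \times 2d$)
  for matched cells and stacks rows for unmatched cells. Silhouettes come
  from `cluster::silhouette`; the test suite checks them against an
  independent from-scratch implementation.

`k` values exceeding the reference size are clipped with a warning.

## Simulating unpaired data

From a paired dataset, `simulate_unpaired()` retains only the second
modality for a uniformly random subset of `round(proportion * N)` cells and
only the first modality for the complement — disjoint cell sets, linked
only by type labels, exactly the structure of a real unpaired design. The
proportion refers to the minor (second) modality by convention
(`which_modality_minor` flips it). Sampling is uniform over cells rather
than stratified by type, so at very small proportions a type can vanish
from one modality; such types are excluded from training batches, and a
stratified mode is available when survival of every type must be
guaranteed. The simulation is applied to the *training* portion only — the
hold-out set stays paired so Recall@k and median rank remain computable.
The permuted-label baseline (`permute_labels()`) destroys the
label-to-profile association while preserving marginal type counts.

## The synthetic generator

`generate_paired()` draws each cell's type from configurable proportions
and a shared latent vector from that type's unit-variance Gaussian, with
centroids placed `separation` within-type standard deviations apart
(orthonormal axes scaled by `separation`/√2 when the latent dimension
allows, random directions rescaled to that mean distance otherwise). Each
modality observes the same latent vector through its own fixed random
linear map plus independent noise — this shared-factor structure is
precisely what the integration model assumes, which makes the generator a
parameter-recovery instrument rather than a realism benchmark. The
negative-binomial option (softplus-transformed means, dispersion 0.3)
emits UMI-like counts so the full normalize → log1p → scale → PCA chain is
exercised; the Gaussian option is for fast metric tests. The generator
does **not** emulate scATAC peak sparsity, batch effects, doublets or
continuous differentiation trajectories, so passing tests demonstrate
correct mechanics and recoverability under the model's assumptions — not
performance on real tissue.

## Problem sizes used by the test suite

The end-to-end parameter-recovery check uses 2000 cells, 5 equiprobable
types, 200 features per modality, latent dimension 10, separation 6 and
negative-binomial counts, with 100 PCs and up to 150 training epochs — a
desk-scale configuration this package adopts as its reference study
condition. The unpairing-trend check uses 500 cells and 80 features per
modality over proportions {0.05, 0.2, 0.5, 1.0} with 3 seeds, where the
mean hold-out Recall@50 is non-decreasing in the proportion (one inversion
within the replicate standard error is tolerated, since 3-seed means are
noisy). Monte-Carlo checks compare against analytic values within three
standard errors.

## Known limitations

* Two modalities only; no three-way integration.
* Cell-type labels are required for training and metrics — annotation
  errors propagate into both.
* The unpaired mode assumes the type vocabularies overlap; types unique to
  one modality are simply dropped from training.
* Discrete types are assumed; continuous processes (differentiation
  trajectories) violate the one-cell-per-type batch design.
* The hand-written optimizer runs on one CPU; it is sized for desk-scale
  data (thousands of cells), not atlas-scale corpora.

## Worked example

```{r, eval = FALSE}
library(modalign)

syn <- generate_paired(synthetic_spec(n_cells = 1000, n_types = 5,
                                      p = 200, q = 150, separation = 6,
                                      count_model = "nb", seed = 1))
split <- make_split(n_cells(syn$dataset), test_fraction = 0.3, seed = 1)
fit <- fit_modalign(subset_cells(syn$dataset, split$train),
                    prep1 = preprocess_config(n_pcs = 50),
                    prep2 = preprocess_config(n_pcs = 50),
                    config = train_config(seed = 1))
autoplot(fit)                     # loss curve
emb <- embed_holdout(fit, subset_cells(syn$dataset, split$test))
evaluate_embeddings(emb$mod1, emb$mod2)

# the full replicated protocol in one call
report <- run_replicates(syn$dataset, n_replicates = 10, base_seed = 1,
                         prep1 = preprocess_config(n_pcs = 50),
                         prep2 = preprocess_config(n_pcs = 50))
aggregate_reports(report)
plot_metric_report(report)
```
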