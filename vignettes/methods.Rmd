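---
title: "Detecting m6A sites with an ensemble of heterogeneous SVMs: models and design choices"
author: "ramESVM maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting m6A sites with an ensemble of heterogeneous SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramESVM)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal modification of
mRNA, implicated in splicing, stability and cell differentiation.
Experimental mapping of m6A sites is expensive, so sequence-based
predictors are used to triage candidate adenosines. `ramESVM` classifies
51-nt RNA windows whose central (26th) residue is an adenosine as
methylated (`m6A`) or not (`non-m6A`), using three support vector machine
voters built on deliberately heterogeneous views of the same window, and a
majority vote to combine them. Training expects balanced positive/negative
window sets; prediction scans arbitrary transcripts for eligible
adenosines (forward strand only — m6A is a mark on single-stranded
transcript RNA, so no reverse-complement scanning is performed).

## The three feature views

**Pseudo dinucleotide composition (PseDNC).** A window of length $L$ is
encoded by its 16 dinucleotide frequencies $f_k$ plus $\lambda$ "pseudo"
components capturing global sequence order:

$$d_k = \frac{f_k}{1 + w\sum_{j=1}^{\lambda}\theta_j}\ (k \le 16),\qquad
  d_{16+j} = \frac{w\,\theta_j}{1 + w\sum_{j=1}^{\lambda}\theta_j},$$

where the tier correlation factor
$\theta_j = \frac{1}{L-1-j}\sum_i \Theta(D_i, D_{i+j})$ averages the
physicochemical dissimilarity
$\Theta(D_i,D_j) = \frac{1}{v}\sum_u [P_u(D_i)-P_u(D_j)]^2$ between
dinucleotides $j$ steps apart. The $v = 3$ properties are dinucleotide
enthalpy (kcal/mol), entropy (cal/(mol·K)) and free energy (kcal/mol) —
quantities that describe RNA secondary-structure stability, relevant
because structure formation antagonizes methylation. Each property column
is standardized (mean 0, SD 1 over the 16 dinucleotides; we use the sample
SD, and the same convention is applied when validating) before entering
$\Theta$, which also makes the mixed units irrelevant. Defaults are
$\lambda = 6$ and $w = 0.9$, the values selected by 10-fold
cross-validation in the method this package implements;
`psedncGridSearch()` reproduces that selection over
$w \in \{0.1,\dots,1.0\}$, $\lambda \in \{1,\dots,10\}$.

Two details were genuinely open and are settings rather than guesses:

* *Counting mode.* The composition part defaults to **overlapping**
  dinucleotide counting (all $L-1$ adjacent pairs), the established PseDNC
  convention. A literal non-overlapping reading (pairs 1–2, 3–4, ...) is
  available via `countingMode = "nonoverlapping"`; on odd-length windows
  such as the 51-nt default it ignores the final unpaired residue. The
  tier factors $\theta_j$ always run over overlapping dinucleotides.
* The vector algebra guarantees $\sum_k d_k = 1$ and $d_k \ge 0$;
  $\lambda = 0$ or $w = 0$ reduce exactly to plain dinucleotide
  composition. These identities are enforced by tests.

**Discriminative substring (motif) features.** All substrings with length
in $[4, 12]$ that occur in training windows of exactly one class become
Boolean presence features. The lower bound 4 is part of the method; the
upper bound is our addition: without a cap every whole training window
becomes a single-use feature. `maxLen = 51` restores the uncapped reading.
By default a substring is dropped when a proper substring of it is already
in the vocabulary on the same side (`minimalOnly`), since on the training
data the superstring's presence implies the substring's presence; this
controls dimensionality without losing training-separability. Mining is
implemented as per-length hashed set differences, provably equivalent to
brute-force enumeration (and tested against it); the minimality filter
uses the fact that a candidate has a retained proper substring exactly
when one of its two (len−1)-substrings is class-exclusive. The vocabulary
is an explicit argument to the encoder, so evaluation code can — and by
default does — re-mine it inside every training fold; sharing one
vocabulary across folds leaks held-out information and is only available
behind an explicit flag.

**Gapped k-mer string kernel.** The third voter never sees explicit
features: the kernel between two windows is the inner product of their
gapped k-mer count vectors, where each $l$-mer contributes one count to
each of its $\binom{l}{k}$ patterns with $k$ fixed letters and $l-k$
wildcards. Equivalently, summing $\binom{l-m}{k}$ over all $l$-mer pairs
at Hamming distance $m \le l-k$ — the closed form used internally, exact
and integer-valued. Defaults $l = 10$, $k = 6$ are the published defaults
of the gkm-SVM family; 51-nt windows make exact computation cheap, so no
approximations are used. Kernel matrices are cosine-normalized
($K'_{ij} = K_{ij}/\sqrt{K_{ii}K_{jj}}$), giving unit diagonal and entries
in $[0,1]$. Kernel values are functions of the sequence pair only — no
fitting is involved — so evaluation precomputes one Gram matrix per
dataset and subsets it per fold without any leakage.

## Classifiers and the vote

Kernels per view: radial basis for the dense 22-dimensional PseDNC
vectors, linear for the sparse Boolean motif vectors, and the precomputed
normalized gkm kernel for the string view. The regularization constant
(and RBF width) are selected by stratified 10-fold cross-validated grid
search *within the training fold only*; the winning setting's CV accuracy
is stored on the classifier. The default grids are
$C \in 2^{\{-3,1,5,9\}}$ and $\gamma \in 2^{\{0,4,8\}}$ — compact ladders
chosen once so that honest per-fold refits (3 classifiers × grid × 10
inner folds × 10 outer folds) stay tractable on a single core. The gamma
ladder is matched to the PseDNC feature scale, the only view that uses
it: PseDNC vectors lie on the probability simplex, their median squared
pairwise distance is a few times $10^{-3}$, and the median-heuristic
kernel width is therefore near $2^8$; a gamma far below that leaves the
radial kernel nearly constant and the voter degenerate. Both grids are
plain arguments for users who want wider searches.

The ensemble vote for class $i$ is $V_i = \sum_k w_k\,f(\mathrm{pre}(C_k),
\mathrm{Class}_i)$ with $f = 1$ on agreement, and the call is
$\arg\max_i V_i$. Weights are uniform by default — the only reading
consistent with the three-voter analysis below — with a
`cv_accuracy`-proportional policy available. Ties are possible only with
non-uniform weights and resolve to the largest-weight voter's label
(first such, in stored order), deterministically.

**Why voting wins.** For independent voters with accuracies
$p_1,p_2,p_3 \in (0.5,1)$ the majority is correct with probability
$P = p_1p_2p_3 + p_1p_2(1-p_3) + p_1(1-p_2)p_3 + (1-p_1)p_2p_3$. At equal
accuracies $q$ this is $3q^2-2q^3 > q$ (since $q(2q-1)(q-1) < 0$ on the
interval), so the ensemble beats any single equally accurate voter.
`votingAccuracyClosedForm()` implements the closed form (validated against
exhaustive 8-outcome enumeration), `simulateVoting()` the Monte Carlo
counterpart. The ensemble is *not* guaranteed to beat $\max(p_k)$ when
accuracies differ — a caveat that matters in practice (below).

## Evaluation

Jackknife (leave-one-out) and stratified k-fold protocols refit the entire
recipe per round — motif vocabulary, hyperparameter search, all three
fits, weights — on the training split only. Metrics are the four
standard ones ($Sn$, $Sp$, $Acc$, $MCC$); an MCC with a zero marginal is
reported as 0 with a warning rather than erroring, so batch reports
survive degenerate folds. `k = n` reduces exactly to the jackknife.
Per-window audit records (truth, final and per-voter labels, voting
scores, fold index) are retained and serializable.

A leave-one-out caveat worth knowing: on a balanced dataset, a voter whose
features carry no signal degenerates toward predicting the training-fold
majority, which in leave-one-out is *always the opposite class* of the
held-out window — an anti-correlated voter, not a random one. With
uniform weights this caps the ensemble below perfection even when the
other two voters are flawless. The effect is intrinsic to the protocol,
shrinks with stratified k-fold at moderate k, and is why the
`cv_accuracy` weighting policy exists.

## The synthetic benchmark generator

`syntheticWindows()` emulates the balanced benchmark design the method
was built for: equal numbers of positive and negative 51-nt windows, each
centered on an A, background residues i.i.d. (uniform by default). Each
positive carries a planted consensus — default `GGACU`, the canonical
methyltransferase context whose single A is the methylated adenosine —
with probability 0.9, jittered up to ±3 positions around the center.
Defaults mirror the package's own end-to-end benchmark conditions.

Two design points:

* *Jitter vs. the central A.* A shifted consensus whose non-A residue
  landed on the center would break either the window invariant (central A)
  or the planted motif. The shift is therefore drawn uniformly from the
  shifts in $[-j, +j]$ compatible with a central A: the motif's A sits on
  the center, or the motif clears the center entirely. For `GGACU` with
  jitter 3 the admissible shifts are $\{-3, 0, +3\}$. Since none of the
  three feature views is position-specific, this discretization does not
  soften the learning problem.
* *Negatives are not screened*: background can produce the consensus by
  chance (≈4.5% of uniform 51-nt windows contain `GGACU`), mirroring real
  negative-sampling noise. `strictNegatives = TRUE` removes such windows
  for separability tests.

What passing synthetic tests does **not** show: real m6A contexts are not
i.i.d. background plus one exact consensus — they carry degenerate motifs,
composition biases and structure. Synthetic results validate the
machinery (encodings, honest evaluation, voting), not biological
performance; for that, train on experimentally mapped windows.

## Numerical and reproducibility choices

* All randomness (fold assignment, generator, simulations) flows from one
  integer seed; SVM fits themselves are deterministic, so identical inputs
  and seed give byte-identical models, reports and archives. Sub-seeds are
  derived arithmetically from the master seed and stay below $2^{31}$.
* Grid-search ties resolve to the first setting in deterministic grid
  order; vocabulary entries are sorted by (length, lexicographic);
  dinucleotides are indexed lexicographically (AA..UU) rather than in any
  table's printed order.
* Degenerate inputs fail fast with typed messages: non-ACGU residues,
  windows without a central A, single-class training folds (reported with
  the round index), too-short sequences for a given $l$ or $\lambda$.
* Model archives are single RDS files containing the property table,
  configs, vocabulary, learned states, weights, seed and a training-set
  fingerprint, version-stamped and validated on load.

## Problem sizes used by the shipped checks

The package's own end-to-end check runs the full honest protocol at
200+200 windows × 10 folds × 5 seeds (about 1.5 minutes per seed on one
core), a deliberately scaled-down analogue of the 1,307+1,307 benchmark
the original method was evaluated on; the leakage control runs the same
pipeline at 100+100 with no planted signal and must stay inside the
3-sigma binomial band around chance. On these conditions the ensemble
typically reaches 0.85–0.90 accuracy with the gkm voter strongest
(~0.91), the motif voter near 0.84 and the composition voter weakest
(~0.67). Note what the planting rate does to the voting gain: the ~10%
of positives that carry no signal at all defeat every voter *jointly*,
and such correlated errors void the independence assumption behind the
$3q^2-2q^3$ analysis — under these conditions the ensemble tracks its
best single voter closely rather than beating it. On data where the
views err more independently (as heterogeneous views on real benchmarks
tend to), the voting gain reappears.

## Known limitations

* The voting analysis assumes independent voters; real voters share the
  training fold and err together on hard windows, so closed-form gains are
  upper bounds.
* Exclusive-substring mining is brittle to label noise: one mislabeled
  window can delete a true consensus from the vocabulary. Frequency-
  thresholded exclusivity would be the natural extension; the strict
  "occurs in exactly one class" reading is what this package implements.
* PseDNC on 51-nt windows estimates 16 frequencies from 50 pairs; its
  voter is the weakest and mainly adds diversity rather than raw accuracy.
* Windows shorter than $l = 10$ or $\lambda + 2$ are rejected rather than
  padded.
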