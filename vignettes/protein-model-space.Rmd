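---
title: "Clade-specific substitution models and the structure of protein model space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-specific substitution models and the structure of protein model space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`protspace` works with the 20-state general time-reversible (GTR~20~)
model of amino-acid substitution. A model is a pair of parameter sets:
a symmetric matrix of *relative exchangeabilities* (REs) — one value
$r_{XY}$ per unordered residue pair, 190 in all — and a vector
$\Pi = (\pi_A, \ldots, \pi_V)$ of equilibrium frequencies. The
instantaneous rate of replacing residue $X$ by residue $Y$ is
$Q_{XY} = r_{XY}\,\pi_Y$; diagonal entries make rows sum to zero, and
the whole matrix is rescaled so the mean rate $-\sum_X \pi_X Q_{XX}$
equals one, which makes branch lengths expected substitutions per site.
Counting parameters, the model has $190 - 1$ free exchangeabilities
(one is absorbed by the overall scale) plus $19$ free frequencies: 208.
The unrestricted 20-state model, which distinguishes $X\!\to\!Y$ from
$Y\!\to\!X$, has $380 - 1 + 19 = 398$; the extra 190 parameters buy
little for the comparative questions this package addresses, which is
why everything here is built on the reversible parameterization.

Among-site rate heterogeneity uses the standard discrete approximation
of a mean-one gamma distribution with shape $\alpha$: $k$ equal-weight
categories (default $k = 4$), each category's rate being the
conditional mean of its probability-$1/k$ bin, computed in closed form
from the incomplete gamma function. The category median is available
as an option (`discrete_gamma_rates(..., method = "median")`) because
tools in this field differ on this point; the mean-of-bin rule is the
default. An optional invariant-site class of weight $p_{\mathrm{inv}}$
rescales the gamma rates by $1/(1 - p_{\mathrm{inv}})$ so the overall
mean rate stays one.

Likelihoods are computed by Felsenstein pruning over unrooted trees,
with site patterns compressed before evaluation. Gaps and ambiguity
codes (`X B Z J * ? .`) are treated as missing data — a partial
likelihood of one over all states. This is a convention, not a
necessity, but it is the convention of essentially every tool in the
field. The compiled core also returns analytic first derivatives of
the log-likelihood with respect to the exchangeabilities, the
frequencies and the branch lengths, obtained from the directional
derivative of the matrix exponential in the eigenbasis of the
symmetrized rate matrix; this is what makes 208-parameter training
practical on a single CPU.

## Training clade models

`train_clade_model()` estimates one GTR~20~(+I)+Γ model jointly from
many alignments, each on its own tree. Using a separate tree per
alignment means discordance between gene trees and the species tree
does not bias the rate-matrix estimate. The procedure alternates:

1. **Per-alignment trees** (`estimate_msa_tree()`): pairwise
   maximum-likelihood distances under the current model (one-dimensional
   optimization per pair, capped at 10 with a warning for saturated
   pairs), neighbor-joining, then joint branch-length optimization.
   A re-estimated tree is kept only if it does not lower that
   alignment's likelihood, so the training trace is monotone.
2. **Shared model** (`optimize_shared_model()`): quasi-Newton (L-BFGS-B)
   maximization over 189 free log exchangeabilities (the A–R pair is
   fixed at 1 for identifiability; the estimate is renormalized to sum
   one afterwards, and no downstream quantity depends on which pair was
   fixed) and 19 additive-log-ratio frequencies, with each alignment's
   gamma shape profiled out by Brent's method between rounds.

Two alternations are the default (`training_config(max_outer = 2)`);
at the scales below the second pass improves the likelihood only
marginally. The default starting model is uniform exchangeabilities
with pooled observed frequencies. Branch lengths live in
$[10^{-8}, 20]$ and $\alpha$ in $[0.05, 100]$; branch-length/shape
optimization stops when a round improves the log-likelihood by less
than $10^{-4}$.

When `use_pinv = TRUE`, the invariant proportion is estimated by
profile likelihood with the gamma shapes re-optimized at every
candidate value. This matters: $+I$ and $+\Gamma$ are strongly
confounded (a small $\alpha$ mimics invariant sites), and coordinate
alternation between $p_{\mathrm{inv}}$ and $\alpha$ crawls along the
resulting likelihood ridge instead of crossing it.

## Model space

Models are compared through `model_distance()`: the Euclidean distance
between exchangeability vectors normalized to sum one. Frequencies are
deliberately excluded (a flag can append them for exploration) — the
point of the comparison is the substitution *process*, and frequencies
are both strongly driven by nucleotide composition and separately
analyzed. `neighbor_joining()` turns a distance matrix into a *tree of
models* — a clustering diagram, not a phylogeny. Negative NJ branch
lengths are clamped to zero with the deficit moved to the sister
branch so path lengths are preserved, and ties in the join criterion
break lexicographically so results are reproducible.

Congruence between a tree of models and a reference topology is
measured by the matching split distance: each tree's nontrivial
bipartitions are encoded as indicator vectors, a pair of splits costs
the smaller of their Hamming distance and its complement, and the
distance is the minimum-cost perfect matching (Hungarian algorithm)
between the two split sets. The implementation restricts itself to
fully resolved trees, where both split sets have $n - 3$ elements;
how to pad the matching for polytomies is a convention we chose not to
guess at, so polytomies raise an error. `random_tree_null()` calibrates
an observed distance against topologies drawn uniformly from all
$(2n-5)!!$ labeled unrooted binary topologies (sequential leaf
insertion on a uniformly chosen edge), reporting the add-one empirical
p-value $(1 + \#\{d_{\mathrm{null}} \le d_{\mathrm{obs}}\})/(n+1)$.
Because the distance is integer-valued, this p-value is conservative
in the presence of ties; the test suite checks calibration through the
randomized probability integral transform, which is exactly uniform
under the null.

## Classification and recall

`best_fit_model()` follows the single-tree protocol: estimate one tree
for the alignment under a reference model (by default the pooled mean
of the candidates; an external reference such as a published general
matrix can be supplied) combined with the alignment's own observed
frequencies (+F) and 4-category gamma rates; then, for every candidate,
keep the topology, swap in the candidate's exchangeabilities, re-optimize
branch lengths and the gamma shape, and score with
$\mathrm{BIC} = k\ln n - 2\ln L$. Re-optimizing branch lengths per
candidate is slightly slower than freezing them from the reference fit
but removes any bias toward candidates resembling the reference; it is
the package's resolution of a genuinely open protocol question, and
every candidate sees the identical number of free parameters, so the
BIC ranking coincides with the likelihood ranking. Ties (within
$10^{-6}$) keep the first candidate and set a flag.

`compute_recall()` scores the results at two levels: *precise* recall
(best model trained on the alignment's own clade) and per-domain match
fractions (best model carrying each domain label). Candidates labeled
`universal` — generalized published models without a clade of origin —
get their own column and are excluded from the named domain fractions,
so domain percentages always refer to clade-bearing models.

## The synthetic-data generator

Real training corpora for this kind of analysis are genome-derived:
thousands of clustered, aligned protein families per clade. The
generator stands in for that corpus at desk scale:

* **Base model.** Exchangeabilities decay exponentially with Grantham's
  physicochemical distance (composition, polarity, volume), giving the
  canonical conservative-fast/radical-slow structure of empirical
  replacement matrices. Frequencies come from the standard genetic
  code with independent base composition at a chosen genomic GC
  content, which reproduces the GARP (GC-rich codons) versus FYMINK
  (GC-poor codons) composition gradient that the analysis module
  regresses on.
* **Clade models.** `perturb_model()` adds independent normal offsets
  (s.d. = `magnitude`) to the log REs and renormalizes. Expected
  distance from the base grows with magnitude, so clade separation in
  model space is a single controlled dial; targeted perturbation of
  named pairs (e.g. only `Y-F`) is available for analyses of specific
  exchangeabilities.
* **Data.** Per clade, `generate_clade_dataset()` draws uniform random
  topologies with i.i.d. exponential branch lengths (mean 0.15 —
  moderate divergence, where exchangeabilities are identifiable without
  saturation), simulates alignments forward from the stationary
  distribution with per-site rate categories, and splits 80/20 into
  training and validation sets. A manifest of per-alignment seeds makes
  any dataset byte-reproducible.

Default scale is 4–8 clades, 20–50 alignments each, 8–16 taxa and
200–500 sites; the studies this emulates used on the order of 1000
alignments per clade, so the package's defaults are an explicit
scale-down. What the generator does *not* emulate: indels (gaps appear
only if injected), heterotachy, non-stationary composition, and
among-protein model variation within a clade — every alignment of a
clade evolves under exactly the clade model. Passing tests on these
data therefore demonstrate the correctness and internal consistency of
the machinery, not that real proteomes are classified with any
particular accuracy; on real data, among-protein variation is the
dominant source of classification error.

## Analysis module

`rank_re_differences()` compares two groups of models on mean
normalized REs: rank 1 is the pair most elevated in group A, rank 190
most elevated in group B, ties broken by pair label; because both
group means are normalized, differences sum to zero and swapping the
groups maps rank $r$ to $191 - r$. `frequency_class_summary()` sums
frequencies over the GARP, FYMINK and remaining residue classes and
fits ordinary least squares against genomic GC%.
`spearman_correlation()` is Pearson correlation on average-tie ranks
with a two-sided $t$-approximation p-value on $n-2$ degrees of freedom —
appropriate at the $n \approx 19$ clades this analysis typically has,
where exact enumeration is infeasible and the normal approximation is
poor. `acidic_basic_ratio()` is
$(\pi_D + \pi_E)/(\pi_R + \pi_K + \pi_H)$; histidine is only weakly
basic at physiological pH, so `include_histidine = FALSE` gives the
stricter R+K denominator.

## Numerical choices and limitations

* Transition probabilities come from the eigendecomposition of the
  symmetrized rate matrix $\mathrm{diag}(\sqrt{\pi})\,Q\,
  \mathrm{diag}(1/\sqrt{\pi})$ — stable, real, and reused by the
  gradient computation. Entries are clamped at zero to absorb
  $10^{-16}$-scale negatives.
* Zero exchangeabilities are storable (and survive PAML round trips)
  but are floored at $10^{-8}$ when a rate matrix is built for
  likelihood work, keeping the chain irreducible; the flooring is
  reported.
* Frequencies read from PAML files are renormalized silently when they
  sum to within $10^{-3}$ of one (printed rounding), and rejected
  otherwise.
* Pair storage order is the PAML convention throughout (lower triangle,
  row-major, alphabet `A R N D C Q E G H I L K M F P S T W Y V`); pair
  labels are row-residue first (`Y-F`, not `F-Y`), and
  `aa_pair_index()` accepts either order.
* The pruning core does not rescale partial likelihoods; with 20 states
  and the package's desk-scale trees (tens of taxa) site likelihoods
  stay far from the double-precision floor. Hundreds of taxa would
  need per-node rescaling, which is out of scope.
* Training problem sizes used in the test suite: parameter recovery on
  20 alignments × 8 taxa × 300 sites; invariant-proportion recovery on
  20 × 500 (the uniform-exchangeability null check also uses 500-site
  alignments, since scatter in rarely informed pairs — those involving
  W and C — dominates the estimate's coefficient of variation at
  shorter lengths); classification on three clades × 25 alignments.

## A worked example

```{r, eval = FALSE}
library(protspace)

base <- synthetic_base_model(gc = 0.5, alpha = 0.8)
specs <- list(
  clade_spec("cladeA", "archaea",
             perturb_model(base, 2, seed = 11, name = "cladeA"),
             n_msas = 12, sites_range = c(200, 300),
             taxa_range = c(6, 8), seed = 1),
  clade_spec("cladeB", "bacteria",
             perturb_model(base, 2, seed = 12, name = "cladeB"),
             n_msas = 12, sites_range = c(200, 300),
             taxa_range = c(6, 8), seed = 2))
ds <- generate_clade_dataset(specs, seed = 5)

## train a model on clade A's training split and classify everything
train_ids <- subset(ds$manifest, clade == "cladeA" & split == "train")$msa_id
msasA <- lapply(ds$clades$cladeA, `[[`, "msa")
fitA <- train_clade_model(msasA[match(train_ids,
                                      sapply(msasA, `[[`, "id"))])

cands <- candidate_set(lapply(specs, `[[`, "model"),
                       clade = c("cladeA", "cladeB"),
                       domain = c("archaea", "bacteria"))
res <- classify_msas(unlist(lapply(ds$clades, lapply, `[[`, "msa"),
                            recursive = FALSE),
                     cands, truth = ds$manifest)
compute_recall(res, cands)
```
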