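---
title: "Species delimitation with Poisson tree processes: model, search and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species delimitation with Poisson tree processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptpdelim)
```

## The model

PTP delimits species on a rooted phylogeny whose branch lengths are in
expected substitutions per site — the direct output of a maximum-likelihood
tree program, with no molecular-clock calibration. The premise is that each
substitution carries a small, constant probability of coinciding with a
speciation event, so speciations form a Poisson process over the
substitution count along the tree, and independently the within-species
branching (coalescent-like) events form a second Poisson process with its
own, typically much higher, rate. Waiting times of a Poisson process are
exponential, so the model reduces to: among-species branch lengths are
i.i.d. exponential with rate $\lambda_1$ (speciations per substitution),
within-species branch lengths i.i.d. exponential with rate $\lambda_2$.

A candidate delimitation is a set of *species roots*: nodes forming an
antichain cover of the tips (every tip has exactly one ancestor-or-self in
the set). A branch is among-species iff its child node lies on a path from
the root to a species root, species root included. With $k$ among-species
lengths $x_1,\dots,x_k$ and $n-k$ within-species lengths
$x_{k+1},\dots,x_n$,

$$L = k\ln\lambda_1 - \lambda_1\sum_{i\le k}x_i
    + (n-k)\ln\lambda_2 - \lambda_2\sum_{i>k}x_i ,$$

with the closed-form MLEs $\hat\lambda_1 = k/\sum_{i \le k} x_i$ and
$\hat\lambda_2 = (n-k)/\sum_{i>k}x_i$ (inverse class means). The delimited
species are the tip sets below each species root.

Two covers are degenerate: the root alone (one species, no among-species
branch) and the all-tip cover (all singletons, no within-species branch).
The two-class likelihood is undefined on an empty class, so these are
enumerated (they are part of the count) but excluded from the ML
comparison. They are instead represented collectively by the single-rate
null model, $\lambda = n/\sum x_i$, $\ln L_0 = n\ln\lambda - n$: the
likelihood-ratio statistic $2(\ln L_1 - \ln L_0)$ against $\chi^2_1$ asks
whether the branch lengths support two rate classes at all, and a large
p-value is read exactly as "one species or every tip its own species".
Inputs on which *only* degenerate covers exist (a cherry, a star tree)
return the null model with $p = 1$ rather than erroring, because placement
pipelines routinely feed tiny per-branch trees.

A *fixed speciation rate* mode supports reference-guided use: when
$\lambda_1$ has been estimated once on a reference phylogeny, candidate
delimitations of a query tree are scored with $\lambda_1$ held fixed and
only $\lambda_2$ re-estimated; species containing a reference tip are then
tagged `known`, the rest `new` (`classify_species()`).

## Counting and enumerating delimitations

The number of antichain covers obeys $D(\mathrm{leaf}) = 1$,
$D(v) = 1 + \prod_{c \in \mathrm{children}(v)} D(c)$; a caterpillar of $m$
tips attains the minimum $m$, and balanced trees grow doubly exponentially
(a balanced 256-tip tree already has a 46-digit count). The recursion is
therefore carried out in exact arbitrary-precision arithmetic (base-$10^7$
digit vectors — the only bignum operations needed are add and multiply,
and no arbitrary-precision dependency is declared), and
`count_delimitations()` returns a decimal string. `enumerate_delimitations()`
materialises the covers by the same recursion and refuses above a cap
(default $10^5$) naming the exact count.

## The search

`delimit()` picks exhaustive search whenever the exact count is within the
cap, so small trees are solved optimally with deterministic tie-breaking
(fewer species first, then the lexicographically smallest species-root id
vector). Larger trees use a two-phase heuristic we designed and validated
against the exhaustive optimum:

1. **Top-down split sweep.** Start with a species root on each child of
   the tree root; repeatedly apply the SPLIT (replace an internal species
   root by its children) that yields the highest likelihood, *whether or
   not it improves the current state*, until no internal species root
   remains; remember every state visited. Passing through non-improving
   states is essential — the likelihood along the split path is not
   monotone even when a far better optimum lies deeper, and a pure
   hill-climb from the root state reached the exhaustive optimum on only
   about half of our two-class benchmark instances.
2. **Hill-climb polish.** From each of the best (up to 25) sweep states,
   strictly improving hill-climbing with SPLIT and MERGE moves (MERGE
   replaces a complete sibling set of species roots by their parent),
   applying the single best improving move per iteration.

Candidate moves shift only the child edges of one node between classes, so
each candidate likelihood is an O(1) update of the class sums; accepted
states are re-scored from scratch to stop floating-point drift. The search
is deterministic; optional random restarts (off by default) draw extra
phase-2 starting antichains from a seeded RNG. On 500 random 8-tip trees
with exponential two-class branch lengths (rates 10 and 100), the heuristic
returned exactly the exhaustive optimum in just over 90% of instances and
by construction can never report a worse state than its initial one; the
acceptance test suite re-measures and prints this agreement rate.

## The simulator

`simulate_dataset()` emulates the classic single-locus benchmark design:
a Yule species tree sets divergence times, a multispecies coalescent draws
a gene tree within it, and the gene tree is handed to the delimiter while
the true tip-to-species map is kept aside for scoring.

* **Yule species tree** (`yule_species_tree()`): from two lineages, the
  waiting time to the next birth with $j$ lineages is
  $\mathrm{Exp}(j\,b')$; after the $n$-th species appears one final
  $\mathrm{Exp}(n\,b')$ interval closes the tree. The scaled birth rate
  $b'$ (study grid 5–160) therefore controls how tightly species
  divergences are packed: for two species the expected root age is
  $1/(2b')$.
* **Multispecies coalescent** (`msc_gene_tree()`): species are populations
  completely isolated after divergence; within a population, $j$ lineages
  coalesce at rate $j(j-1)/2$ per coalescent unit ($2N$ generations), and
  lineage sets merge at each species divergence going rootward.
* **Units.** There is no community-standard definition of how a scaled
  birth rate relates to the coalescent timescale, so the unit convention
  here is this package's own and is stated openly: the
  Yule tree lives on a divergence-time scale, and `pop_size` (default
  0.01) is the population coalescent timescale expressed in
  divergence-time units — a species isolated for $t$ divergence units
  spans $t/\texttt{pop\_size}$ coalescent units. The default was fixed
  a priori on two grounds: (i) at the small end of the $b'$ grid species
  must be isolated for many coalescent units (else no parameter setting
  makes species monophyletic and delimitation is impossible for *any*
  method, contradicting the regime the grid is meant to sweep), and
  (ii) with the default substitution scaling
  (`subs_per_coal_unit = 0.01`) the resulting within/among mean
  branch-length ratio is about 0.15, matching the worked example tree.
  What matters for the benchmark is preserved: $b'$ moves the system from
  clean species separation ($b' = 5$) to heavy incomplete lineage sorting
  ($b' = 160$).
* **Inference error.** Sequence simulation and tree re-inference are
  deliberately replaced by the exact simulated gene tree; an optional
  mean-one log-normal noise factor on branch lengths (`noise_sd`,
  default 0) is a crude stand-in for inference error. Consequently,
  simulation results here characterise the model and search, not the
  robustness of the full sequence-to-tree pipeline — accuracies on real
  data, where the input tree is itself estimated and possibly misrooted,
  will be lower.

Reproducibility: every replicate derives its Yule and coalescent seeds
from the configuration's root seed, and the CLI writes the resolved
configuration (seeds included) as JSON next to its outputs; identical
configurations give byte-identical outputs.

## Scoring against the truth

`nmi()` compares partitions by normalized mutual information with
natural-log entropies and geometric-mean normalization
$MI/\sqrt{H(a)H(b)}$ — the form of the clustering-ensembles literature the
criterion originates from; the arithmetic-mean variant is available via
`normalization = "arithmetic"` for cross-tool comparison, since published
uses of the criterion do not always state the variant. Conventions: both
partitions single-group gives 1 (they are identical), exactly one entropy
zero gives 0. Group ids are immaterial; partitions identical up to
relabelling score exactly 1 (detected by canonical relabelling before any
floating-point work, which also makes `nmi(a, b)` bitwise equal to
`nmi(b, a)`).

## Numerical choices and degenerate inputs

* Branch lengths are floored at `epsilon` ($10^{-10}$, configurable)
  before any likelihood work: inferred trees contain zero-length branches
  which would give infinite rates. Lengths are otherwise used as-is, with
  no rescaling by alignment length.
* The LRT statistic is clamped to 0 when within $10^{-9}$ below it (float
  noise); a genuine inversion of null and alternative is an error.
* Ties in the search are broken toward fewer species, then the smallest
  sorted species-root id vector, making every search mode deterministic.
* A missing branch length anywhere except on the root itself is a
  validation error; the root's own length is ignored. Multifurcations are
  accepted throughout (the count recursion, edge classification and both
  searches use the general over-children forms). The package never
  re-roots: correct rooting is the caller's responsibility, and a
  misrooted tree will misplace the speciation transition points.

## Problem sizes used by the shipped tests

The test suite keeps everything desk-scale: exhaustive/greedy agreement on
500 random 8-tip instances; accuracy sweeps with 20 replicates of 10
species × 5 individuals at $b' \in \{5, 160\}$ (mean NMI ≥ 0.8 at the
small rate and monotone degradation toward the large one — a
property-based check of the delimiter itself; a full pipeline benchmark
would additionally involve sequence simulation and tree inference); rate
recovery from 500 branches per class; Monte-Carlo checks of the Yule root
age and coalescent TMRCA expectations at $10^4$ replicates.

## Known limitations

* Single locus, two rate classes. Heavily oversampled species with tiny
  within-species variation can push the within-rate so high that sparsely
  sampled species fragment into singletons; a third rate class would be
  needed to absorb this, at the cost of a much larger search space.
* The heuristic is validated statistically, not guaranteed: it can miss
  the global optimum, and its quality bar was measured on 8-tip two-class
  instances.
* The simulator draws equal population sizes for all species and no
  migration; its `pop_size`/$b'$ convention is this package's own (see
  above), so absolute accuracy numbers are not comparable across tools
  that scale their simulations differently.
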