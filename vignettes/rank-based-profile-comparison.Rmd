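---
title: "Rank-based comparison of differential expression profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based comparison of differential expression profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankcmp)
```

## Why ranks

Differential-expression results from different platforms, cohorts or
pipelines are not directly comparable: fold changes live on different
scales, p-values reflect different sample sizes, and significance cutoffs
arbitrarily truncate each profile. The only information that survives all
of these differences is the *ordering* of genes. `rankcmp` therefore
reduces every profile to a ranked profile — a bijection between a gene
universe of size $N$ and the ranks $1\ldots N$, rank 1 being the most
upregulated gene — and compares whole orderings.

Two assumptions follow. First, profiles must be placed on a *shared*
universe before any comparison; `intersect_profiles()` restricts each
profile to the intersection of the gene sets and re-compacts its ranks,
preserving relative order. Gene matching is exact, case-sensitive string
equality — identifier conversion and probe collapsing are upstream
concerns, deliberately out of scope. Second, ties in fold change are
resolved by lexicographic gene id. This is arbitrary but deterministic:
two runs on the same input always produce the same ordering on any
machine. Ranking is invariant under strictly monotone transforms of the
fold change, so whether the input is a log2 ratio or a signed test
statistic does not matter as long as larger means more upregulated.

## Merging replicates: the prototype ranked list

Replicate profiles of one biological state are merged into a single
consensus ordering, the prototype ranked list (PRL), by iterated
closest-pair aggregation:

1. compute Spearman's footrule
   $D(x,y)=\sum_i \lvert R(i,x)-R(i,y)\rvert$ between all pairs;
2. merge the closest pair with the Borda mean rule (each gene's score is
   the mean of its two ranks; re-rank by ascending score);
3. replace the pair by the merged profile and repeat until one remains.

Distances are recomputed after every merge, since each merge changes the
pool. The footrule is a true metric on permutations, with maximum
$\lfloor N^2/2 \rfloor$ at the full reversal and expectation
$(N^2-1)/3$ between independent uniform orderings — useful yardsticks when
reading a merge trace. Two deterministic tie rules complete the procedure:
equal minimum distances are broken by the lexicographically smallest sorted
name pair, and Borda score ties by gene id. Merged profiles are re-ranked
to integers after every step so the footrule stays integer-valued, and
each merged profile counts as one profile in later iterations regardless
of how many inputs it absorbed — the merge is a pairwise scheme, not a
weighted average. The trace (`steps`: left, right, footrule) is retained
so the user can see which replicates agreed and which were folded in last.

## RRHO maps

The rank–rank hypergeometric overlap map asks *where* two profiles agree.
For cutoffs $n = s, 2s, \ldots$ down profile $x$ and $k = s, 2s, \ldots$
down profile $y$, the overlap $u$ between the two top segments is compared
with the hypergeometric null
$h(u; N,n,k)=\binom{k}{u}\binom{N-k}{n-u}\big/\binom{N}{n}$. Each pixel
stores a signed tail:

$$
v(n,k)=\begin{cases}
-\log_{10} P(U\ge u) & u \ge nk/N\\
+\log_{10} P(U\le u) & u < nk/N
\end{cases}
$$

positive for more overlap than expected, negative for less. At exact
equality with the expectation the over-tail is used, giving a value of 0
or slightly above — the boundary case is rare and the choice only affects
the sign of a near-zero pixel.

Numerical choices:

- **Log-space tails.** Tails come from `phyper(..., log.p = TRUE)`
  (log-gamma based). For $N$ in the tens of thousands, concordant pixels
  reach $p \sim 10^{-1000}$; a linear-space computation would underflow to
  0 and the map would saturate at `Inf`. In log space every pixel is
  finite.
- **Step size.** The default is $\lceil\sqrt{N}\rceil$, so the pixel count
  per axis grows like $\sqrt N$ and the total pixel count like $N$. A
  smaller step gives finer spatial resolution at quadratic cost.
- **Trailing genes.** Genes beyond the last full step do not get a partial
  bin; the grid stays square with equal-sized bins and the last cutoff may
  be below $N$. (With the default step, at most $2\sqrt N$ of $N$ genes
  are affected, and only in the outermost row/column.)
- **Cutoff direction.** Cutoffs step from the top of both lists. For
  concordant profiles the signal sits on the diagonal, strongest where the
  lists are most reproducible; the bottom-left corner compares upregulated
  ends and the top-right downregulated ends. For a *reversed* pair every
  overlap is at its floor $\max(0, n+k-N)$, so the whole map is
  non-positive: the depletion is extreme mid-grid and fades to exactly 0
  along the outer row/column, leaving the anti-diagonal corners as the
  map's maxima. To display an anti-correlated pair as enrichment, reverse
  one profile first (`rank -> N + 1 - rank`).
- **Multiple testing.** The raw map is reported by default.
  `correct_grid()` optionally applies Benjamini–Yekutieli across pixels —
  BY rather than BH because neighbouring pixels are strongly dependent —
  to the two-tailed $p = \min(1, 2\,p_\text{one-sided})$, preserving
  signs.

`pixel_genes()` recovers the overlapping gene list behind any pixel
(ordered by rank in the first profile), which is the hook for downstream
enrichment: the package deliberately ships no pathway database — pixel
gene lists can be piped to whatever annotation tool the analyst trusts.

## Enrichment-score distances

The signature of profile $x$ at length $s$ is the pair $(p, q)$ of its $s$
top- and $s$ bottom-ranked genes; $s \le \lfloor N/2\rfloor$ keeps them
disjoint. A gene set is scored against profile $y$ with the unweighted
Kolmogorov–Smirnov running sum: walking down $y$'s ordering, add $1/s$ for
a member and subtract $1/(N-s)$ otherwise; the enrichment score (ES) is
the deviation of maximum absolute value, in $[-1, 1]$, with the positive
deviation taken on exact magnitude ties. The walk is evaluated on the
integer numerator $hN - is$ over the common denominator $s(N-s)$ (where
$h$ is the member count after $i$ steps), so the walk ends at exactly 0
and the extremes are exact: $\mathrm{ES}=+1$ iff all members occupy the
top $s$ ranks, $-1$ iff the bottom $s$. This is the membership-only walk —
ranks are the only weights available — not the weighted GSEA variant.

The total enrichment score of $x$ with respect to $y$,
$\mathrm{TES}_{x,y} = 1-(\mathrm{ES}_y(p)-\mathrm{ES}_y(q))/2 \in [0,2]$,
is 0 when $y$ orders $x$'s signature exactly as $x$ does and 2 when it
reverses it. TES is directed; `distance_matrix()` symmetrizes all pairs as
either $D_\text{avg}=(\mathrm{TES}_{x,y}+\mathrm{TES}_{y,x})/2$ or
$D_\text{max}=\min(\mathrm{TES}_{x,y},\mathrm{TES}_{y,x})$ — the latter
calls a pair distant only when *both* directions are, which is the
stricter, conservative reading of the "maximum-distance" convention in the
signature-comparison literature.

The default signature length $s = 250$ follows the prototype-ranked-list
convention for transcriptome-scale profiles. When $2s > N$, $s$ is clipped
to $\lfloor N/2\rfloor$ with a message rather than an error: small
intersected universes are common in cross-platform work and a hard error
would force every caller to recompute the bound. For unrelated profiles
$D_\text{avg}$ concentrates near 1 (each directed ES is near 0), which is
the natural "no relationship" reference when reading a distance matrix.

## Networks and clustering

Distance matrices convert to similarity networks with edge weight $2 - D$,
so the threshold is a *minimum similarity*: raising it can only remove
edges. RRHO-based networks use a scalar per pair; the grid maximum of the
signed map is used — the strongest co-regulation signal anywhere in the
map. This is one defensible scalarization among several (centre pixel,
mean); the maximum was chosen because a localized but strong agreement
(e.g. only the upregulated ends agree) should still produce an edge.
Anti-correlated pairs scalarize to $\le 0$ and drop out at any positive
threshold.

Affinity propagation groups profiles without a preset cluster count by
message passing on the similarity $-D$, preference (self-similarity)
defaulting to the median off-diagonal similarity, damping 0.9, up to 1000
iterations, convergence declared after 100 iterations of a stable exemplar
set. Two implementation details matter:

- **Determinism.** The common cure for message-passing degeneracies is
  random jitter on the similarities; this implementation instead adds a
  tiny *index-ordered* offset ($\sim 10^{-9}$ of the similarity range) to
  the preferences. Exactly interchangeable profiles — which would
  otherwise deadlock into one-point clusters or oscillate — resolve to the
  earliest profile as exemplar, and generic inputs are unaffected, so
  clustering remains equivariant under relabeling whenever the input has
  no exact ties.
- **Degenerate input.** An all-identical set of profiles yields a constant
  similarity matrix on which the update equations carry no information;
  this case is detected and returns a single cluster directly.
  Non-convergence within the iteration budget is reported with a warning
  and the labels implied by the final messages (all `NA` if no exemplar
  ever emerged).

## The synthetic generator

`simulate_profiles()` emulates the input the pipeline is designed for:
groups of replicate profiles of the same biological state, each group
concordant around its own latent ordering, different groups unrelated. Per
group a uniform random base permutation is drawn; each replicate perturbs
the latent score $-r$ (base rank $r$) with Gaussian noise of standard
deviation $\sigma N$ and re-ranks. The single knob $\sigma$ moves smoothly
from identical replicates ($\sigma = 0$ reproduces the base exactly) to
independent permutations (the within-group footrule approaches
$(N^2-1)/3$). The default study condition used throughout the tests is
$\sigma = 0.05$ — replicates that agree strongly but far from perfectly,
the regime where merging is useful — with 5 replicates per group and
universes of 200–500 genes, sizes at which every statistic is exercised
meaningfully while the whole suite runs in well under a minute.

What the generator does *not* emulate: count or intensity noise models,
platform-specific dynamic ranges, missing genes per platform (universes
are complete; intersection is exercised separately), or correlated gene
modules. Passing tests therefore demonstrate the correctness of the rank
statistics and the recoverability of group structure under rank noise —
not performance on any particular real platform mixture.

`make_de_table()` inverts ranking: it synthesizes strictly decreasing fold
changes (cumulative exponential gaps, centred) along a profile's rank
order, so `to_ranked_profile(make_de_table(x))` is exactly `x`. This gives
the file-format layer round-trip fixtures without shipping any data.

## Limitations

- The statistics compare *orderings only*; two profiles with identical
  orderings but wildly different effect sizes are indistinguishable.
  Conversely a profile with many near-zero fold changes gets ranks for all
  of them; intersecting onto informative genes first is the user's call.
- RRHO pixels are strongly dependent; even the BY-corrected map should be
  read as a descriptive picture, not a field of independent tests.
- TES depends on the signature length; $s$ far above the number of
  genuinely regulated genes dilutes the signature with noise and pushes
  all distances toward 1.
- Differential-expression estimation itself (normalization, shrinkage,
  testing) is out of scope: the package starts from a finished
  gene/log2FC table.
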