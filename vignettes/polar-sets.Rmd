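---
title: "Designing sequence-specific minimizers with polar sets"
author: "polarmin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sequence-specific minimizers with polar sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarmin)
```

## The model

A minimizer scheme $(w, k, \mathcal{O})$ samples positions from a sequence
$S$ over the alphabet $\Sigma$ ($\sigma = |\Sigma|$): in every window of
$w$ consecutive k-mers it selects the position of the smallest k-mer under
the total order $\mathcal{O}$, preferring the leftmost on ties. Because
adjacent windows overlap heavily, the same position is usually selected
repeatedly, and the *specific density* — selected positions per k-mer of
$S$ — falls between $1/w$ (a *perfect* scheme) and $1$. We report the
*density factor*, density $\times (w+1)$: a random order (in practice a
seeded hash of each k-mer) achieves a density factor of about $2$ on
random sequences, a perfect scheme about $1$.

When the target sequence is fixed — a reference genome that a mapper
indexes over and over — the order can be specialised to it. polarmin
implements the *polar set* approach. A polar set $A$ with slackness
$s \in [0, 1/2)$ is a k-mer set whose occurrences in $S$ are pairwise at
least $(1-s)\,w$ bases apart, so no window ever contains two members. An
order *compatible* with $A$ (members below all non-members) then selects
every member occurrence, and each one suppresses the selections that a
random order would have made nearby.

### Context energy

A *context* is $w+1$ consecutive k-mers (two overlapping windows), and it
is *charged* when its two windows select different positions. On a
break-free sequence,

$$\#\text{selected} = \#\text{charged contexts} + 1,$$

an identity the package tests exactly. The *energy* $E(c)$ of a context is
its probability of being charged under a uniformly random order:

$$E(c) = \begin{cases} 2/u(c) & \text{last k-mer occurs once in } c \\
1/u(c) & \text{otherwise,} \end{cases}$$

with $u(c)$ the number of distinct k-mers in $c$. We verified this closed
form against exhaustive enumeration of all orderings of the distinct
k-mers on randomized small contexts; that enumeration oracle is frozen
into the test suite. Contexts with all k-mers distinct sit at the baseline
$2/(w+1)$. Summing yields the initial energy $E_0(S)$, the deficit
$D(S) = \sum_c \max(0, 2/(w+1) - E(c))$ over *energy savers* and the
surplus $X(S) = \sum_c \max(0, E(c) - 2/(w+1))$ over *energy spenders*;
the expected number of selections under a random order is $1 + E_0(S)$.

### Link energy and the density sandwich

Two member occurrences $l \le w$ bases apart whose selections interact
form a *link* of energy $2l/(w+1) - 1$; the total $L(S, A)$ over all links
measures how much denser the covered stretches would have been under a
random order. For any compatible order,

$$1 + E_0 - X - L \;\le\; \mathbb{E}[\#\text{selected}] \;\le\;
1 + E_0 + D - L.$$

The same total arises from covered-context bookkeeping,

$$L = \frac{2\,A_{cov}}{w+1} - A_{ele} - A_{seg},$$

where $A_{cov}$ counts contexts containing an uncovered member occurrence,
$A_{ele}$ the uncovered occurrences and $A_{seg}$ the maximal runs of
consecutive occurrence-containing windows. `linkEnergy()` computes both
routes over a shared integer numerator and verifies exact agreement.

**Boundary convention.** The two formulas agree exactly only if $A_{cov}$
counts, for an occurrence at position $p$, the full range of context
starts $p-w \dots p$ — including positions that fall off the end of a
fragment. We adopt that occurrence-relative convention for `LinkStats`,
keeping the identity exact everywhere and the incremental update
constant-time. `densityBounds()` separately resolves fragment ends
exactly: it clips the covered-context count to contexts that exist, counts
a segment's entering and trailing charged contexts only when they exist,
and treats the one genuinely order-dependent case — a linked pair inside
the first or last window of a fragment, where which of its two candidate
charge contexts is used depends on the order — by widening the interval by
one count. Away from fragment ends this reduces to the display above. The
Monte-Carlo sandwich tests exercise both regimes.

### Layered polar sets

One polar set rarely covers a whole genome. Layers fix this: a member
occurrence of layer $j$ must either keep the spacing from everything in
layers $1..j$, or be *covered* — flanked strictly by two occurrences from
layers $1..j{-}1$ at most $w$ apart, where its selection can never occur
anyway. A compatible order ranks layer 1 below layer 2 below … below all
non-members. `validateLayered()` checks the definition literally (all
occurrences, strict flanking); the builder's faster linked-block queries
are provably conservative with respect to it, and a brute-force validation
oracle cross-checks both in the tests.

## The construction heuristic

`buildLayeredPolarSet()` runs several randomized rounds, each producing
one layer:

1. Fix an offset $o$ and visit the positions $t \equiv o \pmod w$ in a
   seeded shuffled order, each k-mer only at its first encounter.
2. Filter: drop k-mers above the round's frequency cap, k-mers that
   collide with themselves (two uncovered occurrences closer than
   $\lceil (1-s) w\rceil$), and k-mers with an uncovered occurrence too
   close to a previous layer. Occurrences covered by previous layers are
   skipped entirely.
3. Insert the k-mer, evicting conflicting current-layer k-mers. In
   *monotonic* rounds an insertion is kept only if the total link energy
   strictly increases (ties rejected).
4. At the end of a round, prune members that form no link. Removing an
   unlinked element never unlinks another, so one pass suffices.

Supporting structures: a suffix array with inverse and LCP heights
answers "all occurrences of the k-mer at $t$" in output-linear time, and
*linked blocks* — one array cell per $\lfloor w/2 \rfloor$-wide block,
each holding at most one selected location thanks to polar spacing —
answer nearest-selected queries within $w$ bases in constant time while
maintaining $A_{cov}, A_{ele}, A_{seg}$ (hence $L$) incrementally. The
monotonic acceptance test compares integer deltas,
$2\,\Delta A_{cov} > (w+1)(\Delta A_{ele} + \Delta A_{seg})$, so it is
exact. Two block structures are kept during a round: a frozen one for all
previous layers (coverage and proximity queries) and a mutable one for the
layer under construction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `w` | — | window size in k-mers; windows span `w + k - 1` bases |
| `k` | — | k-mer length, 1–31 (2-bit packed) |
| `s` | 0.4 | slackness; spacing threshold `ceiling((1 - s) * w)`. Lower `s` gives more energy per link, higher `s` more links |
| `rounds` | 7 | layers built |
| `monotonicTail` | 2 | final rounds that require strict link-energy gain |
| `freqPercentiles` | (0.85, 0.95) | fraction of positions the frequency cap keeps, interpolated linearly across rounds |
| `seed` | 1 | master seed; offsets, shuffles and hash seeds derive from it |

Design choices where the procedure was genuinely open, made once and kept:

* **Spacing threshold** is `ceiling((1 - s) * w)` with an inclusive
  "at least": the integer rule never admits a pair the real-valued rule
  would reject.
* **Charging** compares selected *positions*, which makes the
  selected-equals-charged-plus-one identity exact and testable.
* **Random order** is a seeded 64-bit avalanche hash of the packed k-mer,
  with collisions broken by lexicographic rank — reproducible and
  near-uniform without storing a permutation. Layer rank dominates the
  hash, giving compatible orders for free.
* **Eviction** removes all current-layer occurrences of a conflicting
  k-mer (set semantics); conflicts are found through nearest-element
  peeks, which suffices because current-layer elements already respect the
  spacing.
* **Per-round offsets** are drawn without replacement while
  `rounds <= w`, with replacement otherwise; the frequency percentile
  schedule interpolates linearly. First-encounter deduplication is per
  round: every round reshuffles a fresh congruence class.
* **Coordinates** are 1-based in the R interface, following R and
  Bioconductor convention; the C++ internals are 0-based. Grid offsets
  `o` remain 0-based congruence classes in `0..w-1`.
* **Breaks.** Non-ACGT characters and record boundaries split the
  sequence into fragments; windows and contexts never span them, and
  aggregates sum over fragments (one "+1" per window-holding fragment).
  Member spacing is still enforced on global coordinates across breaks,
  which is conservative.
* **Strand.** Forward strand only; reverse complements are not
  canonicalised. A known limitation for applications that need
  strand-symmetric sketches.

## What the synthetic generators emulate

`simulateSequence()` provides the regimes the theory distinguishes:
`uniform` i.i.d. bases (the random-sequence baseline where the density
factor concentrates near 2 and per-context deficit/surplus are below
$10^{-7}$ at $w = 10$, $k = 15$); `periodic` with period $w$ and $w$
distinct k-mers (the extreme where *every* context is an energy saver);
`planted_perfect`, uniform sequences inside the short-sequence regime
$n < \epsilon\, w\, \sigma^k / 2$ (default $\epsilon = 0.01$), where with
probability at least $1-\epsilon$ the fixed-interval k-mers occur nowhere
else and the compatible minimizer is perfect; and `repeat_mosaic`, blocks
copied from a short core, giving the frequent k-mers and self-collisions
that exercise the filters. What they do *not* emulate: the long-range
repeat structure, GC skew and megabase-scale N runs of real genomes, so
passing tests show correctness of the machinery and the predicted
behaviour in these regimes, not performance claims on any particular
genome.

Problem sizes in the shipped tests were chosen to make sampling error
negligible relative to the quantities checked: megabase uniform sequences
for the density-factor and energy-tail checks, $10^5$ bases for the
end-to-end build, hundreds of bases for the exact combinatorial fixtures.

## Numerical choices

Link-energy totals are compared through integer numerators (multiples of
$1/(w+1)$), so formula-equivalence checks are exact, not
tolerance-based. Context energies use doubles; the all-distinct case
reproduces the $2/(w+1)$ baseline bit-for-bit, making "deficit and
surplus are exactly zero" a meaningful assertion. The suffix array is
built by prefix doubling ($O(n \log^2 n)$) — linear-time construction is
a performance refinement, not a correctness contract; queries are
output-linear either way. Degenerate inputs: sequences shorter than one
window raise errors rather than returning empty results; homopolymer-like
inputs where every k-mer self-collides yield empty layers; empty polar
sets are valid and carry zero link energy.

## Worked example

```{r example}
s <- simulateSequence("uniform", n = 20000, seed = 3)
lps <- buildLayeredPolarSet(s, w = 10, k = 15, seed = 4)
lps

b <- densityBounds(s, lps)
b$count
b$densityFactor

ord <- KmerOrder(layers(lps), seed = 99)
densityFactor(selectMinimizers(s, 10, 15, ord))
densityFactor(selectMinimizers(s, 10, 15, KmerOrder(seed = 99)))
```

On uniform sequences of this size at $k = 15$ almost every k-mer is
unique, so the heuristic approaches the perfect density factor
$(w+1)/w = 1.1$ while the random baseline sits near 2. Repetitive inputs
(`repeat_mosaic`, small alphabets) land in between, with the bounds from
`densityBounds()` tracking the Monte-Carlo selection count.

## Known limitations

* Forward-strand only; no canonical k-mers.
* Alphabet restricted to subsets of ACGT (`sigma` 2–4); k at most 31.
* The heuristic's monotonic variant is quadratic in the worst case
  (in practice close to linear); no attempt is made at the memory
  engineering needed for multi-gigabase references.
* No exact (ILP) polar set optimiser: finding the maximum-link-energy
  polar set is NP-hard, and this package implements the heuristic side
  only.
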