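---
title: "Distance estimation and neighbor-joining reconstruction: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance estimation and neighbor-joining reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodist)
```

This vignette is the package's own account of the methods it implements:
the substitution models and estimators, the agglomeration algorithms, the
file formats, the defaults and why they were chosen, and what the synthetic
data generator does and does not emulate.

## Nucleotide distances

For a pair of aligned DNA sequences the package first reduces the data to
sufficient statistics (`count_pair()`): the number of comparable sites
`valid_sites`, the match weight, the two transition-class weights (A↔G and
C↔T), the transversion weight, and per-base frequency tallies.  Sites where
either sequence carries a gap are excluded (pairwise deletion, the standard
convention for pairwise estimators).

Ambiguity codes are handled by *fractional counting*: a site pairing
symbols with IUPAC candidate sets $S_a$ and $S_b$ contributes weight
$1/(|S_a||S_b|)$ to the substitution category of every pair in
$S_a \times S_b$, and counts as one valid site.  This is the uniform
expectation over the candidate sets; it is deterministic, reduces exactly
to integer counting on unambiguous symbols, and preserves the conservation
law `matches + ts_AG + ts_CT + tv = valid_sites`.  Other weightings (for
example, weighting candidates by observed base composition) are defensible;
the uniform rule is the one implemented and tested.

Four estimators map the proportions to distances in expected substitutions
per site:

* p-distance: $p = 1 - \mathrm{matches}/\mathrm{valid}$;
* Jukes–Cantor: $d = -\tfrac34 \ln(1 - \tfrac43 p)$;
* Kimura two-parameter (the default): with transition proportion $P$ and
  transversion proportion $Q$,
  $d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$;
* Tamura–Nei 1993: splits $P$ into the A↔G class $P_1$ and the C↔T class
  $P_2$ and weighs the three logarithmic terms by base frequencies
  estimated **per pair** from the two sequences' valid sites.  A
  `--global-freqs`-style alignment-wide estimate was considered and
  rejected: per-pair frequencies keep each entry a function of its own
  pair's sufficient statistics, which is what makes row-streaming and
  per-block parallel computation exact.

K2P with $P = p/3,\ Q = 2p/3$ collapses algebraically to JC, and TN93 with
uniform frequencies and $P_1 = P_2 = P/2$ collapses to K2P; both identities
are asserted on parameter grids in the tests.

**Saturation.**  When a logarithm argument is non-positive the correction
is undefined.  Such entries are flagged missing (`NA`) rather than raised
as errors, because a single saturated pair should not abort a large matrix;
the `saturation_distance` argument substitutes a fixed large value when a
downstream consumer (tree building, the binary format) needs finite
entries.  Both behaviours exist in the field; flag-by-default is the
conservative choice.

## Protein distances

`count_pair_protein()` reduces a pair to a $20\times20$ table $N[a,b]$ of
aligned residue pairs (gap and `X` sites excluded).  Two correction
formulas act on the observed proportion of differing sites $p$:
JC-20 $d = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$ and the Kimura
correction $d = -\ln(1 - p - 0.2p^2)$.

The model-based estimators use an empirical reversible rate generator
$Q_{ij} = S_{ij}\pi_j$ built from a published exchangeability table $S$ and
stationary frequencies $\pi$ (WAG, JTT, Dayhoff, VT — selected by its
historical name "MVR" — and LG, shipped as plain-text lower-triangle files
under `inst/extdata/models/`).  $Q$ is normalised so that
$-\sum_i \pi_i Q_{ii} = 1$: distances are then in expected substitutions
per site, and a PAM-style display is just a factor of 100.  The transition
matrix and its derivatives come from the spectral decomposition of the
symmetrised generator $\Pi^{1/2} Q \Pi^{-1/2}$, so
$P(d) = A\, e^{\Lambda d} B$ with constant factors $A$, $B$ — one
eigendecomposition per model, reused for every pair and every $d$.

The log-likelihood of a pair at distance $d$ is
$\ell(d) = \sum_{a,b} N[a,b] \ln(\pi_a P_{ab}(d))$.

* **ML estimator** (`ml_distance()`): Newton–Raphson on $\ell'(d)$ with the
  analytic $\ell''$, bracket $[10^{-6}, 10]$, tolerance $10^{-8}$ on the
  step, at most 50 iterations, initial guess the Kimura correction clamped
  to the bracket.  If the iteration leaves the bracket, meets a
  non-concave point, or fails to converge, a golden-section search on
  $\ell$ takes over — slower but bracket-safe.  An all-identical pair has
  $\ell$ decreasing from the start and returns the lower bound; a
  likelihood still increasing at the upper bound returns it with a
  `saturated` attribute.
* **Expected estimator** (`expected_distance()`): the posterior mean over a
  `distance_prior()`.  The default prior is flat on a 400-point geometric
  grid over $[10^{-4}, 10]$ — a neutral, documented choice; the grid is
  geometric because the likelihood varies on a multiplicative scale in
  $d$.  Likelihood weights are combined with a log-sum-exp shift so that
  long alignments (where $\ell$ is around $-10^3$) cannot underflow.

WAG with the ML method is the default model-based estimator: it is the
first of the model-based options and a common default in comparable tools;
nothing in the package depends on this choice.

## Tree reconstruction

All three methods share the selection criterion
$S(i,j) = (m-2) D(i,j) - R(i) - R(j)$ over the $m$ active nodes (row sums
$R$), the branch-length rule
$l_i = D(i,j)/2 + (R_i - R_j)/(2(m-2))$, and the closed-form three-point
termination.  Exact ties in $S$ break to the lexicographically smallest
pair of original node indices — deterministic and order-independent except
on exact ties.

* **NJ** scans all active pairs each step (cubic total).
* **FNJ** maintains a *visibility set*: one stored candidate partner per
  node, found by a full scan when the node is created.  Each iteration
  evaluates $S$ only on the visible pairs, re-scans the winning node until
  its partner survives its own refresh, and joins the winning pair (always
  a member of the visible set).  After a join, nodes whose partner
  disappeared adopt the newly created node, and the creation scan of the
  new node opportunistically improves other nodes' partners.  The number of
  criterion evaluations is exposed as an attribute; empirically it sits
  near $3n^2$ across $n = 50$–$400$.  The exact bookkeeping of the original
  quadratic-time formulation is not reproduced; the implementation is
  pinned to two testable promises instead — visible-pair membership at
  every join, and exact agreement with NJ on additive matrices.
* **BioNJ** selects pairs and assigns branch lengths exactly as NJ but
  carries a variance store $V$ (initialised to $D$) and reduces with the
  variance-minimising weight
  $\lambda = \tfrac12 + \sum_k (V_{jk} - V_{ik}) / (2(m-2)V_{ij})$,
  clamped to $[0,1]$ and set to $\tfrac12$ when $V_{ij} = 0$ or $m = 3$.
  On additive matrices $D_{ik} - l_i = D_{jk} - l_j$ for the joined cherry,
  so every $\lambda$ gives the NJ reduction and the three methods coincide
  there — which is exactly what the recovery tests assert.

Negative branch lengths are kept by default, faithful to the canonical
algorithms; `min_branch_length = 0` clamps them and transfers the deficit
to the adjacent edge, preserving total tree length.  A two-taxon matrix
yields the single edge split across the serialization root.

## Matrix storage and streaming

Both matrix builders compute the upper triangle row by row with identical
arithmetic in both modes; streaming (`row_sink`) merely discards each row
after the consumer has seen it, so streamed and in-memory values are
bit-for-bit identical — asserted, not assumed.  Streaming does not support
ambiguity counting, matching the behaviour of the memory-efficient pathway
this format family comes from.

The binary format stores `magic FPB1 | version | n | length-prefixed UTF-8
ids | upper triangle as little-endian IEEE-754 singles`.  Four-byte
elements were chosen because the format's purpose is footprint: the payload
for $n$ taxa is exactly $4n(n-1)/2$ bytes ($\approx 18.6$ GB at
$n = 10^5$), which is what makes very large families storable at all, and
single precision (about 7 significant digits) exceeds the statistical
accuracy of any pairwise distance estimate.  Values are quantized once on
write; a second round-trip is bit-identical.  Saturated entries are not
representable — producers must substitute a finite value first, keeping the
payload a pure float lattice.  `partition_rows()` splits the row range into
contiguous blocks of near-equal pair workload (balanced to within the
largest single row) as the hook for external parallelisation.

The XML dialect is this package's own minimal schema (embedded, printable
via `print_schema()`); byte-compatibility with any other tool's XML is not
attempted, since no public schema exists to match.  PHYLIP support
deliberately covers both the strict 10-character name field of the classic
tools and a relaxed whitespace-delimited dialect, because the 10-character
limit is precisely what long modern accessions break; interleaved
vs. sequential layout is auto-detected by line accounting (a first block of
full-length sequences means sequential).

## Bootstrap

`resample_columns()` draws alignment columns i.i.d. with replacement.
`bootstrap_matrices()` emits the original-data matrix first (disable with
`keep_original = FALSE`) followed by the replicates.  Replicate `r` seeds
the generator with `(seed + 1000003 r) mod (2^31 - 1)` — a documented,
explicit substream derivation chosen so that replicate `r` is reproducible
from `(seed, r)` alone and replicates can be farmed out to independent
jobs.  Without a seed, a clock-derived one is drawn and reported on the
message channel.  Columns are resampled as raw symbols, before any
ambiguity handling.

## The synthetic-data generator

`random_tree()` grows an unrooted topology by attaching each new leaf to a
uniformly chosen existing edge (uniform over labelled topologies) and
draws branch lengths i.i.d. exponential with mean 0.1 expected
substitutions per site — a typical magnitude for gene-family alignments;
`evolve_sequences()` draws the root from the stationary distribution and
mutates along each edge site-independently under JC, K2P, TN93 or any
bundled protein model, optionally masking DNA bases with compatible
ambiguity codes at a stated rate.

What this emulates is exactly the regime the estimators assume:
site-independent, homogeneous, reversible evolution on a tree.  Real data
violate most of these — rate variation across sites, compositional drift,
alignment error, indels (not simulated at all).  Passing the recovery
tests therefore shows the estimators are correct *under their own model*,
not that they are robust to model misspecification.

## Problem sizes and numerical tolerances in the tests

The suite checks exact additive recovery on trees of 8–50 taxa (20
matrices), NJ-vs-brute-force agreement up to 12 taxa, DNA parameter
recovery at sequence length $10^5$ (20 replicates per model, 3-sigma band
on the mean), protein ML recovery at length 350 with 200 replicates, ML vs
a two-stage $10^4$-point grid search to $10^{-4}$, spectral log-likelihoods
vs an independent scaling-and-squaring matrix exponential to $10^{-8}$,
and FNJ evaluation counts across $n \in \{50, 100, 200, 400\}$.  These
sizes keep the whole suite under a minute or two on a single core while
leaving each statistical band meaningfully tight.

## Known limitations

* No rate heterogeneity across sites (no Gamma models), no LogDet, no
  model selection.
* FNJ's agreement with NJ is guaranteed (and tested) on additive inputs;
  on heavily non-additive matrices it may join a different pair than NJ,
  which is inherent to restricted-candidate selection.
* The binary format has no representation for missing entries, by design.
* The expected-distance prior is a flat grid; a subjective or empirical
  prior can be supplied through `distance_prior()` but none is bundled.
* Streaming mode excludes ambiguity counting.
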