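# phylodist

Distance-based phylogenetics as a composable toolchain: estimate pairwise
evolutionary distances from DNA or protein alignments, store the resulting
matrices compactly, and reconstruct trees with neighbor-joining methods —
either from R or from the shell, with the pieces connected by pipes.

The package is aimed at people who build phylogenetic pipelines over large
gene families, where the distance matrix — not the tree search — is the
computational bottleneck: the matrix for `n` sequences holds `n(n-1)/2`
entries, and keeping it in text form (or entirely in memory) is what breaks
first as `n` grows.

## What is implemented

**DNA distances** (`distance_matrix()`): p-distance, Jukes–Cantor
`d = -3/4 ln(1 - 4p/3)`, Kimura two-parameter
`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` with transition proportion `P` and
transversion proportion `Q`, and Tamura–Nei 1993, which splits `P` into the
A↔G and C↔T classes and weighs them by base frequencies.  IUPAC ambiguity
codes are counted fractionally (uniform expectation over the candidate-set
product) instead of being discarded; sites with gaps are dropped pairwise.

**Protein distances** (`protein_distance_matrix()`): seven selectable
functions — the 20-state Jukes–Cantor and Kimura corrections on the
proportion of differing sites, and the empirical models WAG, JTT, Dayhoff,
VT ("MVR") and LG used with either the pairwise maximum-likelihood
estimator `argmax_d Pr(a,b|d)` (Newton–Raphson on the analytic derivative
of the log-likelihood, computed from the spectral decomposition of the rate
generator) or the posterior-expected distance `E[d|a,b]` over a flat prior
grid.

**Tree reconstruction** (`nj_tree()`, `fnj_tree()`, `bionj_tree()`):
canonical Neighbor-Joining minimising
`S(i,j) = (m-2) D(i,j) - R(i) - R(j)`; Fast Neighbor-Joining, which keeps a
*visibility set* (one candidate partner per node) so total selection work is
quadratic rather than cubic; and BioNJ's variance-weighted reduction.  All
three recover the generating tree exactly from additive matrices.

**Formats**: FASTA, PHYLIP alignments (strict 10-character and relaxed
names; sequential and interleaved), PHYLIP distance matrices (square and
upper-triangular), Newick, a self-describing XML dialect
(`print_schema()`), and a streaming binary upper-triangular matrix format
(magic `FPB1`) holding 4-byte little-endian floats, written and read one
row at a time.

**Bootstrap** (`bootstrap_matrices()`): seeded column resampling where
replicate `r` is reproducible from `(seed, r)` alone, so replicates can be
distributed across independent jobs.

**Synthetic data** (`random_tree()`, `additive_matrix()`,
`evolve_sequences()`): random unrooted topologies, path-length matrices and
sequences evolved under the supported models, for tests and benchmarks.

## Worked example

```r
library(phylodist)

tree <- random_tree(6, mean_branch_length = 0.1, seed = 42)
aln  <- evolve_sequences(tree, n_sites = 1000, model = "K2P", seed = 43)
D    <- distance_matrix(aln, model = "k2p")
round(D[1:3, 1:3], 4)
#>        t1     t2     t3
#> t1 0.0000 0.1347 0.2390
#> t2 0.1347 0.0000 0.1912
#> t3 0.2390 0.1912 0.0000
write_newick(fnj_tree(D), precision = 4)
#> [1] "(t6:0.1357,(t2:0.04239,(t3:0.11,t5:0.06174):0.03761):0.06608,(t1:0.005409,t4:0.0421):0.01984);"
```

The matrix entries are estimated distances in expected substitutions per
site between each pair of simulated sequences (`t1` and `t2` differ at
about 0.13 substitutions per site after the multiple-hit correction; `t3`
is farther from both), and the Newick string is the unrooted tree Fast
Neighbor-Joining reconstructs from those distances, with branch lengths in
the same units.

The same pipeline from a shell, via the bundled entry point:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "phylodist", package = "phylodist"))')
Rscript $CLI synth --taxa 6 --sites 1000 -s 42 -o family.fasta
Rscript $CLI dnadist -O binary family.fasta | Rscript $CLI treebuild -I binary
```

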