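---
title: "Reconstructing full-length SSU rRNA genes from short reads"
author: "ssurecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing full-length SSU rRNA genes from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The small-subunit (SSU) rRNA gene is the universal phylogenetic marker
for characterizing microbial communities, but it is nearly impossible to
recover full length from short-read shotgun data by de novo assembly:
closely related organisms share long stretches of near-identical
sequence, so assembly graphs fragment into short composite contigs
exactly where taxonomic information is needed.  `ssurecon` takes the
opposite route.  Instead of assembling, it *corrects*: starting from a
large database of candidate SSU sequences, it iteratively maps all reads
to the current candidates, probabilistically assigns multi-mapping reads,
and rewrites each candidate base by base from the weighted read evidence
until the sequences stop changing.  The output is a set of full-length
gene sequences, each with a per-position base probability track, plus an
estimate of each sequence's relative abundance in the community.

## The model

Reads $r$ are modeled as generated by unknown community sequences.  Each
candidate sequence $s$ carries a prior $\Pr(s)$ — its current abundance
estimate — and a per-position distribution $\Pr(n)$ over the four bases.
The fit alternates two steps.

**E-step.** For every read with at least one reported mapping, Bayes'
theorem gives the posterior that candidate $s$ generated it:
$$\Pr(s \mid r) = \frac{\Pr(r \mid s)\,\Pr(s)}{\sum_i \Pr(r \mid s_i)\,\Pr(s_i)},$$
where the sum runs over the candidates with reported mappings for that
read (all others are treated as exact zeros).  The likelihood assumes
independent positions:
$$\Pr(r \mid s) = \prod_k \Pr(b_k \mid s), \qquad
  \Pr(b_k \mid s) = \sum_{n \in \{A,C,G,T\}} \Pr(b_k \mid n)\,\Pr(n),$$
with the quality-aware error model
$\Pr(b_k \mid n) = (1 - p_k)$ if $b_k = n$ and $p_k/3$ otherwise, where
$p_k = 10^{-Q_k/10}$ is the base's error probability.  A base called `N`
is maximally uninformative ($p = 3/4$, emission $1/4$ regardless of the
reference).  The two mates of a pair are scored as one longer read.  All
of this is done in log space with log-sum-exp normalization; a read whose
total probability still underflows falls back to a uniform posterior over
its mapped candidates and is counted.

**M-step.** Priors become posterior means over the $J$ mapped reads,
$\Pr(s) = \tfrac1J \sum_j \Pr(s \mid r_j)$.  Each base distribution is
re-estimated from the aligned reads $j$ with weights $\Pr(s\mid r_j)$:
$$\Pr(n) \propto \sum_j \Pr(s \mid r_j)\,
  \bigl[I\,(1 - p_{k,j}) + (1 - I)\,p_{k,j}/3\bigr],$$
where $I$ indicates that read $j$'s aligned base equals $n$.  The
consensus used for the next mapping round is the per-position argmax.

**Merge and split.** After each iteration, two candidates whose consensus
sequences exceed 97% identity (global alignment, identity over non-gapped
columns) are merged — the lower-prior candidate is absorbed, priors
summed.  Conversely, a candidate whose second most probable base exceeds
10% at strictly more than 4% of positions is split: the twin takes the
minor base at all such positions, and the prior is divided in proportion
to the mean major/minor probabilities there.  This lets one database
entry resolve into multiple coexisting strains.

## Mapping

Mapping is ungapped, both strands, pairs in forward–reverse orientation.
The built-in mapper reproduces a seed-and-filter policy typical of
short-read mappers of the 76-bp era: at most 3 mismatches within the
first 20 bases of each mate, a per-mate cap of 300 on the summed Phred
qualities of mismatched bases, and an insert length within three
standard deviations of the library median.  Internally the seed is cut
into `max_seed_mismatches + 1` disjoint pieces; by pigeonhole, every
alignment the policy can accept must match the reference exactly in at
least one piece, so exact-match indexing of the pieces enumerates every
admissible placement — the mapper is exhaustive with respect to its
policy, which the test suite verifies against a brute-force scan.  For
initialization a single best placement is reported per read (ties broken
uniformly at random, seeded); in subsequent iterations all placements in
the top stratum (minimal mismatch count) are reported.  A SAM/BAM
adapter ingests external alignments instead; because an external mapper
cannot be re-run against the evolving consensus, such mappings are held
fixed across iterations.

Being ungapped, the engine is blind to insertions and deletions; rare
small indel errors can survive in reconstructions.  This is a deliberate
trade for speed and simplicity and matches the scope of the method.

## Initialization, termination, degenerate inputs

The EM is initialized by hard assignment: each read goes wholly to its
single best reference, references with no reads are dropped, and one
M-step is run before the first full iteration.  Iteration stops when no
consensus base changed **and** no prior moved by more than `prior_tol`
(default $10^{-4}$) in each of the last three iterations, or after
`max_iter` (default 40) iterations.  Requiring three consecutive stable
iterations, rather than one, guards against declaring convergence inside
a slowly drifting abundance trajectory.  Candidates whose posterior mass
reaches exactly zero are pruned; positions covered by no read keep their
previous base distribution, so database information is preserved where
no evidence arrives.  Consensus ties go to the previous consensus base,
then alphabetically — determinism matters more than the choice itself.
`report_threshold` only filters output (FASTA, summaries); the active
candidate set is never thresholded.

## Preparing and stress-testing the database

`prepare_db()` reproduces standard reference preparation: sequences
outside 1,200–1,900 bp are dropped and the rest greedily clustered at
97% identity, longest first, each sequence joining the first centroid it
matches.  Identity is computed from a Needleman–Wunsch global alignment
with terminal-gap columns excluded from the denominator; a free-end-gap
alignment was rejected here because a short chance overlap between
unrelated sequences can score near 100% and would corrupt clustering.
`mutate_db()` randomizes exactly `round(0.10 * L)` positions per
sequence (each to a uniformly chosen different base, fully logged),
the standard robustness stress: can the method climb back to the true
sequence from a corrupted starting point?

## What the simulator emulates — and what it does not

`sim_community()` evolves one random ancestral gene along a random
rooted tree (Jukes–Cantor substitutions), rescaled so the minimum
pairwise distance is `min_divergence` (default 0.10 substitutions/site,
comfortably above the 3% species boundary).  The default nine-member
community uses SSU copy numbers (23, 15, 12, 10, 8, 7, 6, 5, 2) in an
evenly mixed community, giving expected abundances from 2.3% to 26.1%
under the copy-number formula
$a_i = c_i g_i / \sum_j c_j g_j$.  `pad_sequences()` adds 1 kb of random
flanking sequence so fragments can straddle gene boundaries, and
`simulate_reads()` draws wgsim-style pairs (uniform fragment start,
Normal insert, mate 2 reverse-complemented) with substitution errors
injected at exactly the rates the assigned quality vectors claim.
Qualities come from a parametric profile (mean Phred decaying linearly
38 → 22 along the read, Gaussian noise sd 4, clamped to [2, 40]) or can
be sampled from a real FASTQ.

Real data differ in ways the generator does not model: correlated and
context-dependent errors, GC-coverage bias, chimeric fragments, indels,
conserved-versus-variable rate structure along the gene, and reference
databases whose errors are not uniformly random.  Passing the synthetic
benchmarks therefore demonstrates the correctness of the inference
machinery under its own model assumptions, not field performance on
arbitrary instruments.

## Evaluation

`match_and_correlate()` pairs reconstructions with truth sequences
(greedy, most abundant first, best global identity, 97% floor —
below-floor reconstructions are reported as *novel*), then computes the
Pearson correlation between estimated priors and expected abundances
with unmatched truth members counted as zero.  `n50()` is the standard
assembly length statistic.  `weighted_unifrac()` computes
$\sum_b \ell_b\,|A_b - B_b|$ over the branches of a supplied rooted
tree, optionally normalized by the abundance-weighted maximum
$\sum_i (A_i + B_i) d_i$; both values are always returned, since
published numbers do not always state which variant was used.  A
leaf-label permutation test (seeded) is available.  Tree inference is
out of scope — trees are consumed as Newick input, and the synthetic
community generator conveniently returns its own generating tree.

## Problem sizes and numerical choices

The benchmarks in the test suite use the study conditions at desk
scale: the nine-member community with 50,000 error-containing 76-bp
pairs (insert 200 ± 25) against a 10%-mutated database, and an uneven
18-member community spanning two orders of magnitude of abundance with
25,000 pairs.  Both converge in well under ten iterations and a few
minutes on one CPU.  Normalization invariants (posterior rows, priors,
base-probability rows summing to one) are checked after every iteration
at $10^{-9}$.  The E/M update pair is verified against an independent
brute-force implementation of the formulas above at $10^{-9}$ on small
instances, and data log-likelihood is checked to be non-decreasing when
the mapping set is held fixed.  Strictly speaking the consensus update
is a generalized-EM step, so monotonicity of the full update is an
empirical property rather than a theorem; with a frozen mapping it holds
on all tested fixtures.

## Known limitations

No indel handling; no chimera screening (a chimeric database sequence
fully tiled by reads can survive — database pre-screening is the
remedy); abundance estimates inherit the usual SSU copy-number
confounding; homopolymer-heavy error models (e.g. pyrosequencing) are
not modeled.  Amplicon data should work unchanged but is untested here.
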