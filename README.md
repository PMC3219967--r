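# ssurecon

Reconstruction of full-length small-subunit (SSU) rRNA gene sequences
and their relative abundances from short-read shotgun sequencing data.

De novo assembly of short reads almost never yields full-length SSU
genes: high sequence conservation between coexisting taxa fragments the
assembly graph exactly where the phylogenetic information lives.
`ssurecon` instead treats a large candidate database of SSU sequences as
a set of hypotheses and *corrects* them with the reads.  Each iteration
maps all reads to the current candidate consensus sequences, assigns
multi-mapping reads probabilistically by expectation maximization, and
rewrites every candidate base by base from the quality-weighted read
evidence.  Candidates that converge onto one another are merged;
candidates showing minor-allele evidence of several strains are split.
The result is a set of full-length gene sequences — each with a
per-position base probability track — and an abundance estimate per
sequence.

The model in brief: each candidate `s` has a prior `Pr(s)` (its
abundance) and per-position base distributions `Pr(n)`.  The E-step
computes `Pr(s|r) ∝ Pr(r|s) Pr(s)` per read over its mapped candidates,
with `Pr(r|s) = Π_k Σ_n Pr(b_k|n) Pr(n)` and the quality-aware error
model `Pr(b_k|n) = 1 − p_k` (match) or `p_k/3` (mismatch),
`p_k = 10^(−Q_k/10)`.  The M-step sets `Pr(s) = (1/J) Σ_j Pr(s|r_j)` and
re-estimates each `Pr(n)` as the posterior-weighted sum of
`I(1−p) + (1−I)p/3` over aligned reads.  Iteration stops when no
consensus base changes and the priors are stable.

The package also ships the surrounding machinery needed to verify the
method end to end: a deterministic ungapped paired-end mapper
(seed/quality-sum/insert policy), a SAM/BAM adapter, reference database
preparation (length filter, greedy 97% clustering, controlled 10%
mutation for robustness tests), a ground-truthed wgsim-style read
simulator with quality-driven substitution errors, and evaluation tools
(abundance matching and Pearson correlation, N50, weighted UniFrac
against a supplied Newick tree).

## Worked example

Simulate a four-member community, corrupt the reference database at 10%
of positions, and reconstruct:

```r
library(ssurecon)

com <- sim_community(n_members = 4, copies = c(5, 3, 2, 1),
                     gene_length = 1200, seed = 11)
round(com$profile, 3)
#> member_01 member_02 member_03 member_04
#>     0.455     0.273     0.182     0.091

db  <- mutate_db(com$genes, fraction = 0.10, seed = 12)$db
rd  <- simulate_reads(pad_sequences(com$genes, 500, seed = 13),
                      com$profile, n_pairs = 8000, seed = 14)

fit <- ssu_em(rd$reads1, rd$reads2, db = db,
              policy = mapping_policy(insert_median = 200, insert_sd = 25),
              seed = 15)
fit
#> SSU gene reconstruction by expectation maximization
#>   8000 reads in, 4058 mapped at the final iteration
#>   4 candidate sequence(s) after 5 iteration(s) (converged)
#>   member_01            prior 0.4606  length 1200
#>   member_02            prior 0.2612  length 1200
#>   member_03            prior 0.1809  length 1200
#>   member_04            prior 0.0973  length 1200
```

The priors estimate the community profile: reads mapped to each
reconstruction, weighted by assignment confidence, as a fraction of all
mapped reads.  Only about half of the input pairs map — the rest come
from the random genomic flanks, as in a real shotgun library.  Matching
the reconstructions back to the (here known) true genes shows the
sequences were recovered from the 90%-identical starting references and
the abundances track the truth:

```r
mc <- match_and_correlate(com$profile, com$genes, fit$consensus, coef(fit))
round(mc$pairs$identity, 4)
#> [1] 1.0000 1.0000 0.9992 0.9992
round(mc$r, 4)
#> [1] 0.9985
```

`summary(fit)` tabulates priors, lengths and ambiguous positions;
`plot(fit)` shows consensus changes and prior trajectories per
iteration; `write_ssu_fasta(fit, "out.fasta")` writes
`>ssu_<k> prior=<p> length=<L>` records; `probability_track(fit, id)`
returns the per-position base probability matrix.  A thin command-line
wrapper with `run`, `makedb`, `mutatedb`, `simulate` and `eval`
subcommands is installed at `inst/scripts/ssurecon`.

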