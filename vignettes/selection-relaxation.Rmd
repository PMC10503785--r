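---
title: "Detecting relaxed selection and pervasive transcription with selax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting relaxed selection and pervasive transcription with selax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

selax implements a comparative pipeline for asking whether a focal clade —
the motivating case is lungfish, whose genomes are the largest known among
animals — shows a genome-wide weakening of purifying selection, and whether
its transcriptome shows the excess of intergenic, non-repeat-associated
("pervasive") transcription that nearly neutral genome evolution predicts.
This vignette is the package's own account of the models and the design
choices behind them.

## The codon model

All selection analyses rest on a GY94-style codon substitution model over
the 61 sense codons of the standard genetic code (ordered lexicographically
over T, C, A, G). The instantaneous rate from codon $i$ to codon $j$ is

$$
q_{ij} \propto
\begin{cases}
0 & \text{more than one nucleotide change, or } j \text{ a stop} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with $\kappa$ the transition/transversion rate ratio, $\omega = dN/dS$ the
selection parameter, and $\pi$ the stationary codon frequencies (`equal`,
`F1x4`, `F3x4` — the fitting default — or `empirical`). Each rate matrix
is rescaled so the expected number of substitutions per unit time is 1 at
stationarity: branch lengths are expected codon substitutions per site,
and in mixture models every site category shares that calibration. The
model is reversible by construction; transition probabilities come from
the eigendecomposition of the $\pi^{1/2}$-symmetrized matrix, and the
likelihood is computed by Felsenstein pruning (in compiled code, with
per-pattern scaling against underflow).

Missing data follow the standard pruning convention: a codon column that
is gapped or ambiguous in a taxon contributes a partial likelihood of 1 at
that tip; columns missing in every taxon are dropped and counted. In-frame
stop codons are a hard error — the screen targets conserved single-copy
orthologs, where a stop indicates a frame or annotation problem rather
than biology.

## Selection intensity k

Relaxation models act on $\omega$ through a branch-level exponent:
on a test branch with selection intensity $k$, a site category with ratio
$\omega$ evolves with effective ratio $\omega^k$. Since most $\omega$ are
below 1 in conserved genes, $k<1$ compresses them toward 1 — relaxation —
while $k>1$ pushes them away — intensification. The limit $k=0$ is full
neutrality, and `apply_k()` defines $0^0 = 1$ so that the $k \to 0$ limit
is continuous at $\omega = 0$.

`fit_relax()` is the hypothesis test: a shared 3-category $\omega$
distribution (constrained $\omega_1 \le \omega_2 \le 1 \le \omega_3$ for
identifiability) is fitted with $k$ fixed at 1 (null) and with a single
free $k \in [0, 50]$ shared by all test branches (alternative); twice the
log-likelihood difference is referred to $\chi^2_1$. The null $k=1$ is
interior to the admissible range ($k<1$ and $k>1$ are both meaningful),
so no boundary-corrected mixture distribution is needed.

`fit_general_descriptive()` profiles a separate $k$ per branch: the shared
distribution is estimated once under $k=1$, then each branch's $k$ is
optimized alone (Brent on $[0,50]$) with all other branches held at 1.
A joint fit of one $k$ per branch would be better identified in principle
but is poorly behaved at desk scale; the profile version is what the
per-branch relaxed-gene fractions (`per_branch_relaxed_fraction()`) need,
namely a ranking of branches by their pull toward $k<1$.

## The gene screen

The per-gene protocol (`fit_gene()`, aggregated by `screen_partition()`):

1. branch lengths and $\kappa$ are estimated under the one-ratio model and
   then held fixed — the two-ratio and relaxation fits re-estimate their
   own $\kappa$ but not the lengths;
2. a two-ratio model estimates $\omega_{fg}$ on the test (foreground)
   branches and $\omega_{bg}$ elsewhere, with a 1-df LRT against the
   one-ratio null;
3. `fit_relax()` tests the same tagging for $k \ne 1$.

Fixing branch lengths after the one-ratio fit keeps the per-gene
optimization tractable and uses the data's own divergence estimates; a
co-estimation switch exists on `fit_branch_model()` for users who want
the joint fit.

A gene is called **relaxed** only when both tests are significant *and*
directionally concordant ($\omega_{fg} > \omega_{bg}$ and $\hat k < 1$),
**constrained** in the mirror case, and **neither** otherwise — the
deliberately conservative intersection rule. Genes whose optimizations do
not converge are **failed** and leave every denominator ("produced an
output" means both fits converged). P-values are Benjamini–Hochberg
adjusted across genes by default (`correction = "none"` reproduces a
raw-p screen); the per-test level is $\alpha = 0.05$.

Swapping the test and reference sets exchanges relaxed and constrained
calls exactly. This is not an accident of implementation: exponentiating
the reference side by $k$ instead of the test side is a reparameterization
of the same model family ($(\omega_i, k) \mapsto (\omega_i^k, 1/k)$
preserves the category constraints), so the optima, the LRT and the
direction of every call mirror precisely. The acceptance suite exercises
this symmetry on a planted gene set.

Partition-level statistics are classical: relaxed-vs-rest proportions are
compared across partitions with Pearson's $\chi^2$ without continuity
correction (so the statistic equals the squared two-proportion $z$), with
Fisher's exact test as the small-expected-count fallback; the
concatenated free-ratio $\omega$ trend uses a two-sided Mann–Whitney test,
exact when both groups are small and tie-free, tie-corrected normal
approximation otherwise.

## Optimization

All fits use box-bounded quasi-Newton optimization (`nlminb`) on
transformed parameters (log scales for $\kappa$, $\omega$ and branch
lengths; stick-breaking for category proportions). Relaxation fits use
three fixed starting points; each start runs to a loose tolerance and the
best is polished to the full tolerance (relative log-likelihood `1e-8`,
parameter tolerance `1e-6`). The alternative model always includes the
null solution with $k=1$ among its starts, which guarantees
$\ln L_{alt} \ge \ln L_{null}$ up to optimizer tolerance — the LRT can
never go negative by more than round-off. Nonconvergence is flagged on
the result, never silent; an alignment with no variable site is reported
as unidentifiable (`converged = FALSE`) rather than fitted. $k$ is
bounded to $[0, 50]$ and $\omega_3$ to $[1, 50]$.

## Private substitutions

`find_private_substitutions()` defines "private" on the observed
alignment: a column yields a record for the focal taxon when the focal
residue is standard, the non-gap background is unanimous for a different
residue (a consensus threshold below 1 is available but off by default),
and at most 20% of the background is gapped or ambiguous. No
ancestral-state reconstruction is attempted — this is the weakest
assumption consistent with counting substitutions private to terminal
lineages, and it makes the operation exactly checkable against a
brute-force column scanner.

Substitutions are classified radical or conservative by whether the two
residues cross a physicochemical class boundary. The published
conservative-radical index table behind the original analysis is not
reproduced in the sources available to this package, so the default
scheme is a standard four-class charge/polarity partition (positive
K/R/H, negative D/E, polar uncharged S/T/N/Q/C/Y/G, nonpolar
A/V/L/I/P/F/M/W); any partition can be supplied as a plain-text table
(`read_category_scheme()`), and all results that depend on the scheme are
reported per scheme. Lineage summaries report counts and radical
fractions (a lineage with zero records reports `NA`, not 0) with pairwise
two-proportion comparisons, BH-corrected.

## Pervasive transcription

Contigs are categorized by two thresholds and a rule order: **coding** if
the longest ORF reaches 100 codons or same-strand overlap with annotated
genes reaches 0.5 (both configurable); otherwise **TE** if the fraction
of the *aligned blocks* (not the intron-inclusive span) covered by repeat
annotation reaches 0.25; otherwise **pervasive**. The pervasive category
deliberately pools intergenic noncoding RNAs with transcriptional
leakage — the pipeline makes no attempt to separate them. Contigs without
genome placement are `unplaced` and excluded from all denominators.

The genomic footprint of pervasive transcription is the strand-ignored
union of *primary-transcript spans* (min-to-max aligned coordinate, i.e.
introns included), computed with `GenomicRanges::reduce()`. Per-tissue
transcriptional effort is the fraction of reads on each category;
all-zero tissues report `NA`. The cross-species statistic is a Spearman
rank correlation of pervasive span against assembled genome size with a
seeded permutation p-value (10,000 permutations by default) alongside the
classical approximation.

Coordinates follow the Bioconductor convention throughout: intervals are
1-based and closed, as in `GRanges`; GFF3 input arrives in that
convention natively and BED input is converted on import by rtracklayer.
Strand is respected only where it is evidence (coding overlap) and
ignored where the question is a genomic footprint (span merging, repeat
overlap).

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with planted
truth:

* `make_gene_set()` simulates per-gene codon alignments on a fixed
  15-taxon tree with a 5-taxon focal clade (`default_screen_tree()`);
  defaults: 50 genes, 20% planted relaxed with $k = 0.3$ on the focal
  clade, $\kappa = 2.5$, site categories
  $\omega = (0.05, 0.35, 1.2)$ with proportions $(0.45, 0.45, 0.10)$ —
  a conserved-gene regime dominated by purifying selection with a small
  nearly neutral tail — and lengths around 300 codons (log-normal,
  clipped to 150–800). Branch lengths are constants scaled so desk-scale
  alignments retain signal without saturating third positions.
* `make_toy_genome()` packs intron-containing genes, 1-kb repeats and
  two-block pervasive transcripts (intron included in the primary span)
  into a 1-Mb chromosome, and allocates per-tissue reads at pervasive
  effort targets spanning 0.2430–0.3868 across five tissues; the exact
  counts mode hits the targets to the read.
* `make_private_sub_fixture()` plants private substitutions under
  enforced background unanimity, with a two-taxon deviation mechanism
  that adds alignment variability without ever creating an unplanted
  private substitution, and a gap model capped below the finder's
  tolerance at planted columns.

Everything is deterministic given the design seed, and file outputs are
byte-identical across reruns.

What passing these tests shows is that the statistical machinery is
correct and well calibrated *under the model*: real alignments add
misalignment, substitution saturation on deep branches, among-site rate
autocorrelation and annotation error, none of which the generators
emulate. In particular, the simulator draws site categories i.i.d. and
evolves them under the same GY94 family the fitter assumes, so parameter
recovery here bounds estimation error, not model misspecification.

## Problem sizes in the test suite

The acceptance checks run the full protocol at sizes chosen for a
single-CPU desk run: 100 random small-tree instances for the likelihood
oracle; 80 null replicates (6 taxa, 300 codons) for the type-I error of
the relaxation LRT, compared against the exact binomial 95% band around
0.05; 15 replicates at 800 codons for power against $k = 0.3$ (threshold
80%) and 20 replicates at 1000 codons for two-ratio direction recovery
(threshold 95%); an 8-gene planted screen for the tag-swap symmetry; all
Mann–Whitney group sizes up to 6×6 and all $\chi^2$ tables with margins
up to 20 against enumeration; 50 random 15×500 alignments for the
private-substitution oracle; and exact checks on the planted toy genome.
`scripts/acceptance.R` recomputes the same quantities at slightly smaller
replicate counts and writes them as JSON.

## Limitations

* Branch lengths are fixed at one-ratio estimates for the two-ratio and
  relaxation fits; genes with very short alignments inherit that noise.
* The general-descriptive $k$ profile is one-branch-at-a-time; branches
  are ranked reliably, but individual $\hat k$ values on non-planted
  branches can hit the $[0, 50]$ bounds when the true signal sits
  elsewhere on the tree.
* The radical/conservative default scheme is one defensible partition
  among several; conclusions about radical fractions should be checked
  against alternative schemes.
* The pervasive category is a residual: anything neither coding nor
  repeat-associated lands there, including unannotated genes.
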