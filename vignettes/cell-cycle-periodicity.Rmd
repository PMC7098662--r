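---
title: "Detecting and comparing cell-cycle transcriptional programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing cell-cycle transcriptional programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclotome)
```

## The problem

A synchronized cell culture released into fresh medium traverses one cell
cycle roughly in step, so genes transcribed at a specific stage show one
oscillation across a time-course transcriptome. cyclotome implements the
complete downstream analysis for such an experiment: finding the periodic
genes from replicate tpm matrices, grouping them into temporal waves tied to
cell-cycle stages, asking how evolutionarily old they are, what functions
they are enriched for, and whether two species' periodic programs overlap
more than chance at the orthogroup level.

The reference design the defaults encode is a culture sampled 16 times at
45-minute intervals starting 2 h after release (a 2–13.25 h window covering
one ~11 h cycle), in two independently grown replicate cultures.

## Periodicity detection

Two rank statistics are computed per gene and combined.

**Cosine-correlation test.** For each candidate period $m \in \{14,15,16\}$
samples and each integer phase lag $l \in \{0,\dots,m-1\}$, the series is
compared with the discretized reference waveform
$r_i = \cos\!\big(2\pi (i - l)/m\big)$ by the tie-aware Kendall correlation.
The score for one waveform is

$$S = \sum_{i<j} \operatorname{sign}(x_i - x_j)\,\operatorname{sign}(r_i - r_j),$$

with reference values equal up to $10^{-8}$ treated as tied. A one-sided
p-value for each waveform comes from the permutation null of $S$; the
reported p is the minimum over the grid multiplied by the number of distinct
waveform hypotheses (45 for the default grid), capped at 1.

**Umbrella test.** A hypothesis is an ordered (trough, peak) pair of phases
on the cyclic phase grid: expression rises monotonically along the circle
from the trough to the peak and falls back. Pairs of samples within one arm
contribute Jonckheere–Terpstra-style concordance with arm position; pairs
straddling the arms contribute nothing (ranks cannot be ordered across
arms). This catches asymmetric rise/fall shapes a cosine correlate
under-scores, and — because the arms wrap the period boundary — profiles
whose trough falls inside the sampled window. With a 16-sample period there
are 240 distinct hypotheses; the reported p is again Bonferroni over that
count.

**The permutation null.** Both scores are linear functionals of the pairwise
sign pattern of the series, so the null distribution depends on a series only
through its tie pattern. Nulls are therefore computed once per tie pattern and
shared across all genes: for the usual tie-free series, one set of sampled
permutations (default $2\times10^4$, seeded) serves the whole matrix, which
is why no "fast approximate" mode is needed. The sampled permutation set is
closed under rank complement, making the antiphase symmetry exact: negating a
series gives the identical p with the best lag shifted half a period. For
series of seven or fewer points the null is enumerated exactly over all $n!$
permutations; the test suite verifies this enumeration against a naive
independent oracle to $10^{-12}$.

**Conservatism.** Bonferroni across a grid of strongly correlated hypotheses
(adjacent lags share most of their concordant pairs) makes the combined
p-values conservative: on pure noise roughly 1–1.5% of genes fall below
0.05 rather than 5%. This mirrors the behaviour of the published tools the
procedure re-implements. The pipeline consumes *ranks*, not p-value
magnitudes, so the conservatism does not affect gene selection; the test
suite asserts the conservative direction (never anti-conservative) at several
thresholds.

**Ranking and selection.** Within each dataset the two tests' p-values are
Benjamini–Hochberg adjusted across genes and each gene is ranked per test on
the adjusted values (ties broken by raw p, then gene id); the final
periodicity rank is the sum of the two ranks. Genes must rank within the
loose cutoff (default 2000) in *both* replicates, and the strict-cutoff best
(default 800) of those candidates by the replicate-average dataset's rank are
selected; genes can be forced in or out by hand. Where the source analyses
disagreed on whether ranks derive from BH- or Bonferroni-adjusted values, the
main-text convention (BH) is the default and `adjust = "bonferroni"` is
available in `rank_and_combine()`.

Other conventions resolved here: the average dataset is the element-wise mean
of tpm *before* any normalization (rank tests are invariant to per-gene
monotone transforms, so z-scoring before testing would change nothing);
expression filtering keeps genes with mean tpm strictly above 1 in every
replicate; z-scoring for clustering uses the population SD (divide by $n$) —
any consistent convention gives identical ranks and distances up to scale.

## Temporal clustering

Selected genes' z-scored average profiles are clustered by agglomerative
hierarchical clustering on Euclidean distance cut at $k = 5$ (the linkage is
not fixed by the source analyses; complete linkage is the default, with
average and Ward available), or by seeded k-means with 25 restarts. Clusters
are re-indexed by ascending peak time of their mean profile and labelled with
the cell-cycle stage whose window contains the peak (G1/S 2–3.5 h, S
3.5–5.75 h, G2/M 6.5–7.25 h, M 9.5–11 h, G1 wrapping 11 h → 2 h); a peak in
a gap between windows is labelled `unassigned` with a warning. Agreement
between two clusterings is reported per cluster pair as
$|a_i \cap b_j| / \min(|a_i|, |b_j|)$.

## Gene ages by Dollo parsimony

Under a single-gain, losses-only model the most parsimonious origin of a
gene family is the most recent common ancestor of the species possessing it,
so `dollo_origin()` computes the presence-set MRCA directly rather than
wrapping an external gene-content program; the test suite checks this
equivalence against a brute-force minimizer over all single-gain placements
on random trees. Ages are integer classes counted along the focal species'
lineage from 0 (species-specific; the default for genes in no orthogroup) to
the root — for the reference tree: 0 species-specific, 1 Filozoa, 2 Holozoa,
3 Opisthokonta, 4 Unikonta, 5 Paneukaryotic. Per-cluster age enrichment uses
two-sided Fisher tests on 2×2 tables against the whole-transcriptome
background, Bonferroni-corrected over all cluster-by-age cells of the run,
with direction from the odds ratio.

## Term enrichment

Annotations are propagated to ancestor terms (true-path rule) over a generic
DAG (is_a plus configurable relations, read from OBO). `term_for_term()` is
the classical one-sided hypergeometric test. `parent_child_union()`
conditions each term on the union of its parents: the background for term
$t$ is restricted to genes annotated to at least one parent, which removes
enrichment merely inherited from a parent; a term annotating exactly its
parents' union can never be flagged. Cluster enrichment is computed against
the whole periodic program as the population — a deliberate, unusual
background that asks "what distinguishes this wave among periodic genes",
not "among all genes". Bonferroni counts only terms actually tested (roots
and unannotated terms are skipped and logged).

## Cross-species overlap

For a species pair, $C$ counts orthogroups present in both species, $p_1$
and $p_2$ their periodic orthogroups within $C$ (an orthogroup is periodic
for a species if at least one member gene is), and the chance expectation
for the shared count is $A_{exp} = p_1 p_2 / C$. The one-sided test uses
$X \sim \mathrm{Binomial}(C,\ (p_1/C)(p_2/C))$ — the unique binomial on the
common universe with mean $A_{exp}$; the trial count is not fixed by the
source description, so the hypergeometric alternative (Fisher on the 2×2 of
$p_1 \times p_2$ within $C$) is available via `method = "fisher"` for
sensitivity analysis. The same statistic applies to one-to-one ortholog
pairs with $C$ the number of pairs. Species gene lists are first capped at a
genome fraction (10% for compact genomes, 5% for large ones) by
`apply_species_threshold()`. Note the degenerate saturated case: if every
common orthogroup is periodic in both species, the expectation equals the
observation and the p-value is 1 — sharing cannot exceed chance when chance
already predicts everything.

## The synthetic world

`simulate_timecourse()` generates the stated world the analysis assumes:
16 samples at 0.75 h from 2 h, two replicates, 10% periodic genes, one
oscillation (11 h period) over the window. Periodic genes follow

$$x_g(t) = b_g + A_g \cos\!\big(2\pi (t - \varphi_g)/P\big)\, e^{-\lambda (t - t_0)} + \varepsilon_{g,t},$$

clipped at zero: a log-normal baseline $b_g$ (median 50 tpm, sdlog 1 —
typical of the expressed fraction of a bulk tpm matrix), uniform phase,
amplitude $A = 3\sigma$ by default (`amplitude_snr`; with $\sigma = 0$ the
value is read as an absolute tpm amplitude so a noiseless world still
oscillates), i.i.d. Gaussian noise $\varepsilon$ with $\sigma = 5$ tpm drawn
independently per replicate, and exponential amplitude damping at
$\lambda = 0.05\,\mathrm{h}^{-1}$ emulating the progressive loss of culture
synchrony. $\lambda$ is a free parameter of the stated world — no
measurement quantifies the desynchronization rate. A tenth of the
non-periodic genes drift linearly (total drift $3\sigma$ over the window,
random sign) to exercise specificity against monotone trends. What a green
recovery test does *not* establish: real tpm noise is heteroscedastic and
correlated along the series, real profiles are not cosines, and replicate
cultures share batch structure; the generator emulates none of that.

`simulate_orthogroup_universe()` draws per-species presence and periodic
labels independently (the null of the comparative module) or plants a stated
fraction of orthogroups as periodic everywhere;
`simulate_family_history()` evolves a family from a chosen origin with
per-branch loss, the focal lineage immune so the family stays observable.

## Numerical choices and edge cases

* Permutation p-values use $(1 + \#\{S^\ast \ge S\})/(B + 1)$, so $p \in
  (0, 1]$; exact enumeration uses the plain tail fraction (the identity
  permutation is in the enumeration). The floor of a combined p is
  `n_hyp / (B + 1)` — resolving signals below 0.05 with the umbrella's 240
  hypotheses needs the default $B = 2\times10^4$.
* All-tied (constant) series get p = 1 and a `degenerate` flag; constant
  rows are rejected by the z-scorer by name.
* Ties among waveforms at the permutation floor are broken by the
  normalized score (tau-b for the cosine grid), so a noiseless cosine
  reports its generating period and lag.
* Ranks break ties by raw p then lexicographic gene id; every rank column
  is a permutation of `1..n_genes`, making reruns bit-identical.
* All randomness flows from explicit integer seeds through fixed
  sub-streams per stage; identical configs reproduce identical outputs.

## Limitations

Periods are expressed in samples, not hours; the defaults assume the
16-sample/0.75 h design and must be rescaled for other designs. No spectral
methods, amplitude estimation or de-trending are provided. Orthogroup tables
must come from a single joint inference — mixing id spaces across runs is
rejected rather than reconciled. The Dollo model ignores gene transfer and
re-gain; ages are only as good as the input tree and orthogroups.
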