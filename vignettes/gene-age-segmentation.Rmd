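---
title: "Methods: long-range gene-age segmentation of prokaryotic chromosomes"
author: "chromoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-range gene-age segmentation of prokaryotic chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoseg)
```

# The problem

Gene order in bacteria and archaea is scrambled beyond the operon scale even
between close relatives, yet chromosomes are not homogeneous: genes inherited
from a clade's common ancestor ("ancient" genes), recently acquired genes
("young" genes), and genes with lethal knockout phenotypes each cluster into
large alternating chromosomal segments of roughly 100–300 genes. `chromoseg`
provides a tested pipeline for detecting this mesoscale structure and for
exploring, by simulation, which evolutionary forces can create and maintain
it.

The pipeline has four layers:

1. **Gene-age classification** from genus-wide pangenome commonality
   (`curateAssemblies()`, `clusterCommonality()`, `genusThresholds()`,
   `classifyGeneAges()`, `representativeGenome()`).
2. **Circular segmentation** of a binary-tagged gene string with a smoothed
   skew profile refined by greedy BIC merging (`segmentChromosome()`), plus a
   chi-square uniformity test and an enrichment summary.
3. **Pattern statistics**: multiscale structural complexity (`mscProfile()`)
   and circular autocorrelation (`circularAutocorrelation()`).
4. **Generative models**: selection against multi-gene disruption of
   essential genes (`evolveDisruption()`) and differential gene mobility with
   translocation attractors (`simulateMobility()`), with a staged fitting
   procedure (`fitMobilityModel()`).

Synthetic-data generators (`synthBlocky()`, `synthPermute()`,
`synthBlockShuffle()`, `synthPangenome()`) provide ground-truthed inputs and
null controls, so the whole pipeline is exercisable without any sequence
database.

# Gene-age classification

A genus is represented by a boolean assembly × protein-cluster presence
matrix (the product of an upstream protein clustering step, which is outside
this package's scope). The *commonality* of a cluster is the fraction of
assemblies carrying at least one member; paralog counts are ignored. Highly
common clusters likely descend from the genus ancestor, rare clusters are
likely recent acquisitions, so commonality serves as an operational gene-age
proxy.

**Curation.** Identical assemblies are removed, then outliers are filtered
with the commonality-peak rule: with $k$ assemblies and $n_i$ clusters
present in exactly $i$ of them, $i^* = \arg\max_{i = \lceil k/2 \rceil..k}
n_i$ locates the rightmost peak of the commonality curve, and only assemblies
carrying every cluster of that peak bin are kept. Ties in the argmax are
broken toward larger $i$, which prefers the stricter core set. The operation
is idempotent; applying it to a set with no cluster in the upper half of the
commonality range is an error (`no-core-peak`), since such a "genus" has no
core to anchor the filter.

**Thresholds.** For each genome, the commonality values of its clusters are
collected and the inclusive tertile thresholds are taken: $Q_L$ is the
$\lceil n/3 \rceil$-th smallest value and $Q_H$ the $\lceil n/3 \rceil$-th
largest. "Inclusive" means the boundary value itself belongs to the outer
class, so the bottom and top thirds each cover at least a third of the list.
With this symmetric convention the ancient and young classes each approach
1/3 of a genome's gene complement, which is the design goal of the
classification. (A one-sided lower-quantile reading of the 2/3 threshold
would make the ancient class two-thirds of all genes, contradicting the
tertile construction, so it is not used.) Genus-wide thresholds pool the
per-genome lists; a genome contributes one value per cluster it carries.

**Classification.** A gene is *ancient* when its cluster's commonality is
$\ge Q_H$ (inclusive), *young* when strictly below $Q_L$, *intermediate*
otherwise. Genes mapping to clusters absent from the curated matrix are an
error, not silently intermediate — silent coercion would bias the young
class. The *representative genome* of a genus minimizes the Euclidean
distance between its per-genome thresholds and the genus-wide pair, with
lexicographic tie-breaking for determinism.

# Circular segmentation

Any binary gene attribute defines a circular 0/1 string $a_1..a_N$ with $M$
tagged genes. To handle circularity, the string is duplicated around the
midpoint $K = \lfloor N/2 \rfloor$ (duplicated order: original indices
$K{+}1..N, 1..N, 1..K$), and the skew profile

$$s_i = s_{i-1} + a_i - M/N, \qquad s_0 = 0$$

is computed over the $2N$ duplicated positions. Rising runs mark
above-average local tag density. Since each window of $N$ consecutive
duplicated increments sums to zero, $s_N = s_{2N} = 0$ exactly.

The profile is smoothed with a Gaussian kernel $K_j = e^{-(j/b)^2/2}$ over
$j = -3b..3b$; the default bandwidth $b = 40$ genes suppresses operon-scale
variation while leaving the 100-gene-scale structure intact. Out-of-range
indices are clamped to the ends of the duplicated profile; this only affects
positions outside the central window that the next step consumes, where the
duplicated profile is exactly periodic. Chromosomes whose duplicated profile
is shorter than the kernel support ($2N < 6b + 1$) are rejected rather than
smoothed with a degenerate window.

**Initial boundaries** are the local extrema of the smoothed profile
restricted to one full copy of the chromosome (duplicated indices
$N-K+1..2N-K$), mapped back to gene coordinates. An extremum is a sign
change of the first difference; plateaus collapse to their leftmost
position, making the boundary set deterministic and independent of
evaluation order. No prominence filtering is applied beyond the smoothing
itself. With no extrema the chromosome is a single segment.

**Greedy BIC merging.** A tiling into $k$ segments with $n_i$ genes and
$m_i$ tagged ($p_i = m_i/n_i$) has binomial log-likelihood
$L = \sum_i [\, m_i \ln p_i + (n_i - m_i)\ln(1 - p_i)\,]$ (with
$0 \ln 0 := 0$) and information cost $B = (2k-1)\ln N - 2L$: a circular
$k$-tiling has $k$ boundaries and $k-1$ free densities. Each adjacent pair
(circularly, so segment $k$ can merge with segment 1) is scored by the cost
after merging, $B_i = (2k-3)\ln N - 2L'_i$; the best improving merge is
applied (ties to the smallest segment index) and the procedure repeats until
no merge improves $B$. $B$ strictly decreases at every applied merge, so the
loop terminates in at most $k-1$ steps. The greedy step is verified in the
test suite against an exhaustive evaluation of all adjacent merges.

**Testing and summarizing.** Under uniform tag density the expected count in
segment $i$ is $m'_i = n_i M/N$ and
$\sum_i (m_i - m'_i)^2 / m'_i \sim \chi^2_{k-1}$. Segments with
$p_i > M/N$ form the *enriched* class; exact ties go to the depleted class
(ties have measure zero on real data but the rule must be fixed). The
enrichment factor is the ratio of mean densities between the classes; if a
class is empty the factor is reported as `NA` rather than a fabricated
number. On random permutations of realistic chromosomes the whole pipeline
returns a single uniform segment in ≈99% of draws, so any reported
multi-segment structure is unlikely to be a smoothing artifact.

Coordinates are 0-based half-open gene-index intervals internally; BED
export converts to base pairs when the gene table carries coordinates, and a
segment wrapping the origin is split into two BED records sharing a name.

# Pattern statistics

**Multiscale structural complexity.** For each scale $\lambda$ from 1 to
$\lfloor n/2 \rfloor$, the chromosome is smoothed by circular rolling means
with windows $\lambda$ and $2\lambda$, and the profile value is the mean
absolute difference between the two smoothed sequences. A window of exactly
$\lambda$ terms is used (indices $k..k{+}\lambda{-}1$); the printed-style
formula that sums $\lambda + 1$ terms while dividing by $\lambda$ is treated
as an off-by-one typo. The scale range stops at $\lfloor n/2 \rfloor$ so the
$2\lambda$ window never exceeds the chromosome. Coin-flip sequences peak at
small $\lambda$; block-structured sequences peak near the characteristic
block size. The distance between two profiles (equal $n$ only) is the mean
absolute difference over all shared scales — the full range, since
truncation would discard exactly the large-scale signal the models differ
in. Both the profile and the autocorrelation below are invariant under
rotation and tag complementation.

**Circular autocorrelation.** $R_t$ is the Pearson correlation between the
string and its circular shift by $t$, computed exactly via FFT
cross-products (integer-valued for 0/1 input, so no numerical tolerance is
needed at the zero crossing). The *zero-correlation lag* is the smallest
$t \ge 1$ with $R_t \le 0$ — non-positive, by the definition of the
statistic — and serves as a rough characteristic cluster size. Because the
lags sum to a negative constant, a zero crossing always exists for
non-constant input; constant strings are a `zero-variance` error.

# Model 1: protection of essential genes

A circular chromosome has $N$ genes, $M$ essential. A disruption event hits
a block of $k \ge 2$ adjacent genes and is lethal iff the block contains an
essential gene; the lethal fraction $f$ is the proportion of the $N$
circular windows that are lethal. Closed forms bound $f$: a single
contiguous essential block gives $f = (M + k - 1)/N$, maximal dispersion
gives $f = Mk/N$. With $r$ disruption events per genome per generation,
survival is $e^{-rf}$, the selection coefficient of a rearrangement
$G_0 \to G_1$ is $s = e^{r(f_0 - f_1)} - 1$, and fixation follows the Moran
origin-fixation formula

$$P = \frac{1 - e^{-s}}{1 - e^{-N_e s}},$$

which returns exactly $1/N_e$ in the neutral limit (a series-limit branch
guards $|N_e s| < 10^{-8}$ against 0/0, and the deep deleterious tail
$N_e s < -700$ switches to the asymptotic form $e^{(N_e-1)s}$ to avoid
overflow). At $s = -3.5\times10^{-4}$ and $N_e = 10^4$ fixation is ≈9.2-fold
below neutral — the canonical example of weak selection on a single
translocation.

The evolution move relocates a uniformly chosen gene to a uniformly chosen
position among the $N$ slots of the rebuilt circle; identity moves are
allowed. This is the simplest reading of "random gene to random location"
and makes the proposal distribution symmetric. Acceptance uses the raw
fixation probability without rescaling, so the neutral acceptance rate is
$1/N_e$ per proposal; callers wanting faster equilibration increase the
step count rather than inflating the probability, which would distort the
relative rates of neutral and selected moves. Under strong selection
($r(k-1)N_e/N \gg 1$) the contiguous-block count decreases almost
monotonically and the essential genes consolidate into a single block;
because the final merges are rate-limited by neutral diffusion at $1/N_e$
per proposal, runs at the canonical scale ($N = 100$, $M = 30$,
$N_e = 10^4$) use several times $10^8$ proposals. The simulation core is
compiled (Rcpp) and draws from R's RNG, so trajectories are exactly
reproducible under a seed.

For $k = 2$ the lethal-window count equals $M$ plus the block count, so
evolution is neutral with respect to block *positions*: this model produces
solid blocks, not the fuzzy density-0.5–0.7 segments seen in real genomes —
which is precisely the qualitative gap that motivates model 2.

# Model 2: differential mobility and translocation attractors

Genes are low-mobility (relative translocation rate 1; $M$ of them) or
high-mobility (rate $1+\beta$), and $a$ of the high-mobility genes are
*attractors*. A translocation step samples a gene by mobility weight,
removes it, and samples a destination intergenic region (IR) of the
$(N-1)$-gene intermediate with weight $1 + \alpha e^{-d/\gamma}$, where $d$
is the circular gene-distance from the IR to the nearest attractor (IRs
flanking an attractor have $d = 0$, measured along the shorter arc). The
gene's class and attractor flag travel with it: attractors are intrinsic
gene labels, not fixed coordinates, so an attractor's basin moves when it
does. The vacated position is closed before destination sampling. One edge
case the formulation leaves open: if the only attractor is itself the
translocating gene, the intermediate has no attractor and the destination
falls back to a uniform draw for that step. Attractors are ordinary
high-mobility genes and can be selected for translocation at the
high-mobility rate.

$\alpha$ may be negative down to $-1$ (mild repulsion): the fitting
parameterization $\alpha = e^{\alpha'} - 1$ spans $(-0.9, 999]$ so that the
destination multiplier $1 + \alpha$ covers several orders of magnitude in
both directions while staying positive. Snapshots of the low/high-mobility
string (1 = high) are recorded at the end of each epoch (default 500 epochs
× 5000 steps).

Typical regimes (5–20 attractors, 1–2 orders of magnitude destination bias,
low-mobility genes several-fold less mobile) produce alternating fuzzy
segments — mobile genes pile up around attractors, immobile genes accumulate
in between — reproducing the enriched-segment densities around 0.5 and
enrichment factors around 3 that the segmentation layer reports on such
equilibria. With $\beta = 0, \alpha = 0$ the model reduces to uniform
shuffling and the segmentation returns a single segment; with $a = 1$ a
single young region forms (two segments).

# Fitting the mobility model

The objective is the complexity-profile distance between simulation
snapshots and the target chromosome, summarized per parameter set as the
inclusive 0.1-quantile of the per-epoch distances (with 500 epochs, the 50th
smallest): a low quantile rewards parameter sets whose equilibrium visits
the target's pattern without penalizing burn-in. $N$ and the low-mobility
count are taken from the target; $\gamma$ is fixed at 1 (basin width was
found to matter little).

- **Stage 1**: 2000 uniform samples of $(a, \beta', \alpha')$ with $a$
  integer in $[1, 30]$, $\beta' \in [\ln 10^{-4}, \ln 30]$,
  $\alpha' \in [\ln 0.1, \ln 1000]$, each scored by a fresh simulation.
- **Stage 2**: $a$ is fixed to the *minimum* attractor count among stage-1
  solutions within 5% of the best goodness ("approximately equivalent" needs
  a cutoff; 5% keeps the set small without collapsing it to the single best
  draw), then a 30×30 log-spaced grid over
  $(\beta, \alpha)$ is scored. The grid landscape shows hyperbola-like
  valleys of near-equivalent $\beta$–$\alpha$ trade-offs, and the grid
  matrix is returned for inspection.
- **Stage 3**: $\alpha$ is fixed at 100 and a 1-D log-spaced search over
  $\beta$ (same resolution as the grid) returns the final optimum.

Stage-2/3 evaluations reuse the stage-1 simulation schedule, since no
separate schedule is specified. All search sizes (`n_samples`,
`epoch_steps`, `n_epochs`, `grid_n`) are configurable downward; the
defaults match the full procedure, while the test suite runs a reduced
schedule (a 200-gene target, 12 random samples, 12 epochs of 800 steps, a
4×4 grid) that completes in seconds and still verifies reproducibility,
the final-stage optimality invariant, and that the fitted model beats the
neutral model on a model-generated target.

# Synthetic data: what it emulates, and what it does not

`synthBlocky()` draws alternating enriched/depleted blocks with
per-gene Bernoulli tags. The realistic preset mirrors the printed
young-segment statistics coherently — enriched blocks of 120–210 genes at
density 0.50–0.67 with enrichment factors 2.6–4.2, depleted blocks of
180–320 genes, overall tagged fraction ≈ 1/3 on chromosomes of 2000–5000
genes. The tiling ends with a depleted block that absorbs the remainder of
the circle: a naive "truncate the last block" rule would create sliver
blocks and same-class circular adjacencies whose ground-truth boundaries no
segmentation could recover, making recovery assertions meaningless.
Segmentation recovers the generated boundaries within twice the smoothing
bandwidth in ≥90% of seeds at these settings.

`synthPermute()` destroys all positional structure; `synthBlockShuffle()`
permutes the maximal runs within each tag class, preserving the run count
and run-length multisets exactly (the alternation constraint is kept, so no
two same-class runs become adjacent) — a null that keeps local cluster
sizes but destroys long-range arrangement.

`synthPangenome()` draws per-cluster carriage probabilities from a mixture
(cloud near 0.1, optional shell near 0.5, core at 1) and samples presence
independently per assembly, resampling empty rows/columns. The `tertile`
preset balances expected per-genome complements across the components
(cloud : shell : core cluster counts 10 : 2 : 1), so about a third of each
genome's genes falls in each commonality class.

What the generators do *not* emulate: phylogenetic correlation of
presence/absence within a genus, operon-scale correlation of tags between
neighboring genes, replication-strand asymmetries, and multi-partition
genomes. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the algorithms under the stated generative
assumptions, not the biological conclusions themselves, which require real
genus-scale data through the same interfaces.

# Numerical choices and conventions

- Inclusive tertile quantiles are order statistics ($\lceil n/3 \rceil$-th
  from each end), not interpolated quantiles.
- $K = \lfloor N/2 \rfloor$ for odd chromosome lengths.
- $0 \ln 0 := 0$ in all binomial likelihoods, so pure segments
  ($p_i \in \{0, 1\}$) are handled without special cases.
- Extremum detection uses first-difference sign changes with plateaus
  collapsed to their leftmost point; merge ties go to the smallest segment
  index; enriched/depleted ties go to depleted.
- The Moran formula uses `expm1` throughout, a $1/N_e$ branch for
  $|N_e s| < 10^{-8}$, and an asymptotic branch for $N_e s < -700$.
- Autocorrelation cross-products are computed by FFT and rounded to exact
  integers before normalization.
- All stochastic components draw from R's RNG (including the compiled
  cores), so `set.seed()` or the functions' `seed` arguments make every
  result byte-reproducible.

# A short worked example

```{r example, eval = FALSE}
set.seed(1)
out <- synthBlocky(blockySpec(3000), seed = 1)
seg <- segmentChromosome(out$chromosome)
seg
chisqUniformity(seg)$p_value
enrichmentSummary(seg)$enrichment_factor

ctrl <- synthPermute(out$chromosome, seed = 2)
nSegments(segmentChromosome(ctrl))   # 1: no structure survives permutation
```

# Known limitations

- Segmentation assumes a single circular partition; multi-partition genomes
  are handled by independent per-partition runs through the gene-table
  interface.
- The disruption model treats all non-lethal events as exactly neutral and
  keeps $N$ and $M$ fixed (no gain, loss, or inversion).
- The mobility model moves one gene at a time; operon-scale block
  translocations and inversions are not modeled.
- The fitting procedure is a derivative-free staged search; it
  characterizes the objective landscape (including its flat valleys) rather
  than guaranteeing a global optimum, and its defaults are computationally
  heavy at full scale.
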