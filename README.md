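# chromoseg

Long-range segmentation of prokaryotic chromosomes by gene age and
functionality.

Bacterial and archaeal gene order is scrambled beyond the operon scale even
between members of the same genus, yet chromosomes carry large alternating
segments — low hundreds of genes — significantly enriched in either
evolutionarily conserved ("ancient") or recently acquired ("young") genes,
and similarly in essential genes. `chromoseg` is an R package for detecting
this mesoscale structure and for simulating the evolutionary processes that
could produce it. It is aimed at comparative genomicists working with
genus-scale pangenomes and at modelers studying gene-order evolution.

## What it computes

**Gene-age classes.** From a genus-wide assembly × protein-cluster presence
matrix, each cluster's *commonality* (fraction of assemblies carrying it) is
computed after deduplication and a commonality-peak curation step
(`i* = argmax_{i≥k/2} n_i`). Genes are classified by inclusive tertile
thresholds `Q_L`, `Q_H`: ancient if commonality `≥ Q_H`, young if `< Q_L`,
intermediate otherwise — so each outer class covers about a third of a
genome's genes.

**Circular segmentation.** Any binary gene attribute defines a circular 0/1
string. The cumulative skew profile `s_i = s_{i-1} + a_i − M/N` (computed on
a duplicated copy of the circle) is smoothed with a Gaussian kernel
(bandwidth `b = 40` genes); its local extrema seed a segmentation that a
greedy merge refines under the Bayesian Information Criterion
`B = (2k−1)·ln N − 2L`, with `L` the binomial log-likelihood of the tiling.
Uniformity is tested by `Σ (m_i − m'_i)² / m'_i ~ χ²(k−1)`; segments are
summarized by enrichment factors and tagged-gene capture.

**Pattern statistics.** Multiscale structural complexity (mean absolute
difference between rolling means at scales λ and 2λ; its peak locates the
characteristic block size) and circular autocorrelation with its
zero-correlation lag.

**Evolution models.** (1) A Moran origin-fixation simulation of selection
against multi-gene disruption of essential genes: `k`-gene events are lethal
iff they hit an essential gene; fixation of a single-gene relocation follows
`P = (1−e^{−s})/(1−e^{−Ne·s})` with `s = e^{r(f0−f1)} − 1`. (2) A
differential-mobility model with translocation attractors: genes translocate
at rate 1 or `1+β`, destinations are drawn with weight `1 + α·e^{−d/γ}`
around attractor genes; this reproduces the fuzzy enriched/depleted
segmentation of real chromosomes. A staged random + grid search fits model 2
to a target chromosome by complexity-profile distance.

Synthetic generators (blocky chromosomes with ground truth, permutation and
block-shuffle nulls, U-shaped pangenomes) make the whole pipeline testable
without external data.

## Worked example

```r
library(chromoseg)

set.seed(1)
out <- synthBlocky(blockySpec(3000), seed = 1)   # blocky chromosome + truth
seg <- segmentChromosome(out$chromosome)
seg
#> Segmentation: k = 14 segments over 3000 genes (1024 tagged)
#>   logLik = -1669.05, BIC = 3554.27

chisqUniformity(seg)$p_value
#> 2.89e-62                       # tag density is decisively non-uniform

enrichmentSummary(seg)$enrichment_factor
#> 3.16                           # enriched vs depleted density ratio

nSegments(segmentChromosome(synthPermute(out$chromosome, seed = 2)))
#> 1                              # permuted control: no structure left

zeroCorrelationLag(out$chromosome)
#> 101                            # ~ characteristic cluster size in genes
zeroCorrelationLag(synthBlockShuffle(out$chromosome, seed = 3))
#> 11                             # block-shuffled null loses long-range order

(1 / 1e4) / moranFixation(-3.5e-4, 1e4)
#> 9.174238                       # weak selection: ~10-fold below neutral
```

The 14 segments alternate enriched/depleted, matching the 14 generated
blocks, and every recovered boundary sits within 46 genes (about the
smoothing bandwidth) of a true block edge. See the methods vignette
(`vignettes/gene-age-segmentation.Rmd`) for the model details, parameter
conventions and numerical choices.

A thin command-line shell wraps the same functions:

```sh
Rscript exec/chromoseg synth blocky --n-genes 3000 --seed 5 --out-dir out/
Rscript exec/chromoseg segment --genes out/synthetic.tsv --out-dir out/
```

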