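# glycomine

Resistance-guided genome mining of bacterial genotoxin clusters using
HTH_42-superfamily DNA glycosylases as marker self-resistance genes.

## The problem

Biosynthetic gene clusters (BGCs) that produce DNA-damaging natural products
usually carry their own resistance genes. One such mechanism is base-excision
repair by AlkZ/YcaQ-family (HTH_42) DNA glycosylases, which unhook or excise
the producer's own genotoxin-DNA adducts. Because these glycosylases sit
*inside* the clusters they protect, they can be used in reverse: find the
glycosylase, and you have found a candidate genotoxin cluster.

`glycomine` implements the analysis stack for this mining strategy over large
genome sets:

* **Subfamily classification.** Candidate proteins are classified by their
  catalytic motif, located by pairwise alignment against reference anchors
  and verified in place:

  | subfamily | motif | behaviour |
  |-----------|------------|-----------|
  | YQL | Q&Phi;D | conserved, single copy, never near clusters |
  | AZL | (Q/H)&Phi;Q | diverse, multi-copy, enriched in BGCs |
  | AZL2 | H&Phi;(S/T)(D/E) | YQL-like distribution, AZL-like sequence |

  (&Phi; is an aliphatic residue, A/V/L/I/M by default.) Homology-search hits
  are pre-filtered at e-value &le; 1e-4, identity &ge; 25% and coverage
  > 75%.

* **Cluster proximity.** For each homolog gene, the signed shortest distance
  (bp between closest interval boundaries, 0 on overlap; positive on the 5'
  side of the cluster) to the nearest BGC on the same scaffold within 2 Mbp.
  A gene is *inside* a cluster when it overlaps it, lies within 2 kb, or has
  at most 5 genes between itself and the cluster boundary. Distance
  distributions are summarised (median/quartiles) and compared between
  subfamilies with a chi-square test on landmark distance bins.

* **Census.** Per-genome copy numbers, copy-number frequency spectra,
  YQL/AZL coincidence tables, and pairwise one-way ANOVA of copy counts.

* **Neighborhood.** The five nearest genes on each side of a focal gene, a
  keyword-based functional categorisation (metabolism / signaling &amp; cell
  function / genetic information processing), and inside-vs-outside category
  ratios.

* **Clade conservation.** Mean root-to-tip branch lengths per clade on a
  rooted tree, and mean pairwise percent identity/similarity on an
  alignment.

* **Kinetics.** Single-turnover glycosylase time courses fit to
  `P(t) = A(1 - e^(-kt))`; lag-time and percent-survival dose-response
  series fit to the four-parameter Hill form
  `response = min + (max - min) / (1 + (IC50/dose)^h)`; tangent-method lag
  estimation from growth curves; fold-change ratios of IC50s.

* **Synthetic data.** A generator that builds multi-scaffold genomes, BGC
  intervals, motif-bearing proteomes and assay curves with a complete
  ground-truth manifest, so the entire pipeline is testable without any
  downloads.

## Worked example

Generate a 20-genome synthetic set with known ground truth and run the full
pipeline:

```r
library(glycomine)

gs <- generate_genome_set(simulation_config(n_genomes = 20, seed = 1))
genomes <- lapply(names(gs$annotations), function(g)
  list(annotation = gs$annotations[[g]], bgcs = gs$bgcs[[g]]))
names(genomes) <- names(gs$annotations)

run <- run_pipeline(genomes, gs$proteins, gs$references)
run
#> glycomine pipeline run
#>   proteins classified: 41
#>   YQL: 21 (51.2%)
#>   AZL: 17 (41.5%)
#>   AZL2: 3 (7.3%)
#>   UNCLASSIFIED: 0 (0.0%)
#>   genes with a nearest BGC: 41 (inside: 13 )

distance_summary(run$proximity[run$proximity$subfamily == "AZL", ], "AZL")
#>   subfamily  n n_unassigned      mean median   q25 q75 mean_abs median_abs
#> 1       AZL 17            0 -2198.588      0 -1651   0     2300        416
```

The AZL genes sit at a mean of 2.3 kb from their nearest cluster (many at
distance 0, i.e. inside), while YQL genes are all &gt; 20 kb away — the
planted contrast the generator encodes, recovered by the pipeline with zero
discrepancies against the manifest.

Kinetics on noisy synthetic assay data (generating rate 0.8 min&#8315;&sup1;,
survival IC50s 48.1 and 11.1 uM):

```r
assay <- generate_assay_data(sigma = 0.02, seed = 1)
fit_single_exponential(assay$time_courses$q43a$time,
                       assay$time_courses$q43a$fraction_product)
#> Single-exponential fit: P(t) = A (1 - exp(-k t))
#>   k = 0.7936 min^-1
#>   A = 1.018, RSS = 0.000621 on 8 points

sv <- fit_ic50_survival(assay$survival_curves$hedh4$dose,
                        assay$survival_curves$hedh4$survival)
sv$ic50
#> [1] 50.32
```

A shell entry point for single-genome runs is included at
`inst/scripts/run_pipeline.R`.

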