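---
title: "Resistance-guided glycosylase mining: models and methods"
author: "glycomine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistance-guided glycosylase mining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## Scientific background

Bacterial secondary metabolites that damage DNA (alkylators, cross-linkers,
intercalators) are encoded by biosynthetic gene clusters (BGCs) that also
carry self-resistance genes. DNA glycosylases of the HTH_42 superfamily are
one such resistance mechanism: they excise the producer's own genotoxin-DNA
adducts, initiating base-excision repair. Within *Streptomyces* these
proteins split into subfamilies with sharply different genomic behaviour —
a conserved, single-copy, cluster-independent subfamily (YQL, after
*E. coli* YcaQ) and a diverse, multi-copy, cluster-enriched subfamily (AZL,
after *S. sahachiroi* AlkZ), plus a smaller hybrid clade (AZL2). Because AZL
genes mark their clusters, classifying the subfamily of every HTH_42 homolog
in a genome and measuring its distance to the nearest predicted BGC is a
genome-mining strategy for genotoxin discovery. `glycomine` implements that
analysis and the supporting biochemistry fits.

The package consumes outputs of the external tools a practitioner would run
first — homology search hit tables, GFF3 gene annotations, BGC interval
calls from a cluster predictor, alignments and trees — and never re-runs
those tools itself.

## Coordinate conventions

All internal coordinates are 0-based half-open `[start, end)`. GFF3 is read
and written as 1-based inclusive; BED as 0-based half-open. The converters
are exact inverses, pinned by round-trip tests. Gene identity is taken from
`locus_tag`, then `ID`, then `protein_id`, then a deterministic synthetic id
(scaffold + ordinal) — public genome annotations mix these styles, and a
fixed priority order keeps reruns reproducible. Strand `"?"` is allowed
because BGC intervals and some features are unstranded.

## Motif classification

Subfamily membership is decided by a 3- or 4-residue catalytic window:

* YQL: `Q` – aliphatic – `D`
* AZL: `Q/H` – aliphatic – `Q` (variants QxQ and HxQ)
* AZL2: `H` – aliphatic – `S/T` – `D/E`

The aliphatic set defaults to A/V/L/I/M — a conservative reading of the
observed logos; it is configurable (`aliphatic =`) because the boundary of
"aliphatic" is a judgement call. The third positions of the three patterns
(`{D}`, `{Q}`, `{S,T}`) are disjoint, so no window can match two patterns;
the test suite verifies this exhaustively over all 8,000 trigrams.

**Window location.** Short motifs occur by chance (about 1 in 800 random
trigrams matches the AZL pattern), so the window is not found by scanning
the raw sequence. Instead the query is globally aligned (BLOSUM62, affine
gaps 10/0.5) to a reference anchor whose catalytic position is known, and
the query residues aligned to the anchor's catalytic columns are read off.
The motif is then verified at that anchored position, tolerating up to two
columns of alignment jitter — at AZL-level divergence (~50% substitutions)
a global alignment occasionally shifts the catalytic columns by one, and
the verification step recovers the planted window in such cases. A
4-residue window (for AZL2) is read as one extra aligned column. An
anchor-free regex-scan mode (`mode = "scan"`) is retained as an explicit
fallback for use without anchors, with the chance-match caveat documented.

When several anchors yield classifiable windows, the higher alignment score
wins; exact ties break toward the AZL anchor (arbitrary but fixed). Hits
are pre-filtered at e-value &le; 1e-4 (inclusive), identity &ge; 25%
(inclusive) and coverage &gt; 0.75 (strict); the boundary behaviour of all
three cutoffs is pinned by tests. A minimum-length filter is available for
excluding truncated sequences, but the package does not claim to reproduce
manual curation of pseudogenes.

## Cluster proximity

The distance between a gene and a BGC is the gap between their closest
interval boundaries, 0 for any overlap; under half-open coordinates,
touching intervals also have gap 0. The sign is positive when the gene lies
on the lower-coordinate (5') side of the cluster in scaffold orientation —
clusters are unstranded, so the scaffold is the only available frame.

The nearest BGC is the same-scaffold cluster minimising |distance| among
those strictly closer than 2 Mbp; ties break toward the 5' side, then
lexicographic cluster id. Genes with no qualifying cluster are reported
unassigned rather than dropped. A gene is **inside** a cluster when it
overlaps it, lies within 2 kb, or has at most 5 annotated genes strictly
between itself and the facing cluster boundary — a disjunction of
sufficient conditions. Intervening genes are counted on the facing side
only, as features fully contained in the open gap; genes straddling a
boundary are not counted. The gene-rank alternative (both flanks jointly)
was considered and rejected as inconsistent with per-side neighbor
semantics.

Distance distributions are compared with a classical (uncorrected)
chi-square test on a shared binning of |distance|. The default bins are the
analysis' own landmarks — `{0}` (inside), (0, 2 kb], (2 kb, 20 kb],
(20 kb, 100 kb], (100 kb, &infin;) — and are configurable; all-zero columns
are dropped and the binning is recorded with the result. The test is
undefined below two non-empty bins and errors explicitly there.

## Census and coincidence

Per-genome copy counts are tallied from classified calls only, so census
totals conserve the number of classified proteins. Copy-number frequency
spectra normalise over genomes carrying at least one copy of the subfamily
(&ge;5 copies binned together); `include_zero = TRUE` switches to an
all-genomes denominator. Pairwise subfamily comparisons use classical
one-way ANOVA on per-genome counts including zero-count genomes by default
— whether zeros belong in the groups is genuinely open, so the same flag
controls both conventions and the choice travels with the result. With two
groups, F equals the squared pooled t statistic; the tests assert this
identity on random group pairs.

## Neighborhoods

"Nearest five genes on each side" is by gene rank order on the scaffold,
not bp distance, matching open-reading-frame counting; fewer are returned
near scaffold ends. Functional categories are assigned by a shipped
keyword-rule table (first match wins) into metabolism, signaling/cell
function, genetic information processing, or unknown. Single-assignment is
the default because it conserves counts (category totals equal neighbor
totals); a multi-count mode replicates Venn-style counting of
multi-annotation proteins, and outputs are labelled by mode rather than
silently mixing conventions.

## Clade conservation

Mean root-to-tip path length (sum of branch lengths root&rarr;leaf,
averaged over a clade's leaves) is a simple per-clade rate proxy. The tree
must be rooted; unrooted input produces an error directing to the provided
midpoint rooting. Whether published per-clade values of this kind are means
or medians on a midpoint-rooted tree is typically unstated, so cross-study
comparisons should be qualitative (clade A > clade B) rather than numeric.

Pairwise identity is the fraction of columns where both members are
non-gap and equal, over columns where both are non-gap; similarity
additionally counts substitution-matrix-positive pairs (BLOSUM62 by
default; the matrix name is recorded in the output). Columns gapped in
either member are excluded from that pair's denominator by default; an
all-columns denominator is available behind `gap_mode = "all"`.

## Kinetic and dose-response fits

* **Time courses**: `P(t) = A (1 - e^{-kt})`, no offset — the assay
  measures fraction product from zero. Bounds `k >= 0`,
  `0 <= A <= 1.05`. When the first observation already sits at &ge;95% of
  the fitted amplitude, the rate is reported as a lower bound
  ("complete at the earliest time point") rather than a point estimate;
  flat traces flag the rate unidentifiable.
* **Lag dose-response**:
  `lag = min_lag + (max_lag - min_lag) / (1 + (IC50/c)^h)` — increasing in
  dose, with the dose-0 limit equal to `min_lag` and the response at
  `c = IC50` exactly the min/max midpoint (both asserted analytically in
  tests).
* **Survival dose-response**: the same four-parameter form with the dose
  ratio inverted, decreasing from its dose-0 maximum; a flat ~100% series
  is flagged "no inhibition".
* **Lag from growth curves**: the geometric tangent construction — the
  steepest log-linear segment's tangent intersected with the baseline OD
  (minimum of the first three readings). A curve never exceeding twice
  baseline returns a no-growth sentinel at the final time point.

All fits are bounded Levenberg–Marquardt least squares with a deterministic
5-point log-spaced multistart over the rate or IC50 (plus an initial-slope
heuristic for the exponential), objective tolerance 1e-10, no random
restarts. Noiseless synthetic data reproduce generating parameters to 1e-6
relative; IC50 fits are exactly dose-scale equivariant. Standard errors
come from the local Jacobian.

## The synthetic-data generator

The generator builds the study conditions the analysis is designed for, as
fixed defaults:

* 100 genomes whose per-genome copy-number spectra give a 49/43/8%
  YQL/AZL/AZL2 mix (YQL and AZL2 ~90–95% single copy; AZL frequently
  multi-copy, present in ~45% of genomes). Copy numbers are allocated by
  exact largest-remainder quota and shuffled across genomes, so the planted
  mix is realized for every seed.
* AZL placements split 40% inside a cluster (distance 0), 35% at the
  cluster edge (gap 0.2–2 kb), 25% mid-range (gap ~4–12 kb with &ge;6
  intervening genes); mid-range gap draws are rescaled so the realized mean
  |distance| over all AZL genes equals the configured 2.3 kb. YQL and AZL2
  genes are planted beyond 20 kb (gaps rescaled to mean 25 kb) with &ge;6
  intervening genes. Each planted gene gets its own scaffold with its own
  cluster, which makes the manifest distance exact by construction;
  multi-hundred-scaffold draft assemblies are the norm for this genus, so
  many short scaffolds are realistic.
* Proteins are derived from per-subfamily base sequences (sharing a common
  ancestor so anchor alignment is meaningful) mutated at per-subfamily
  rates — YQL conserved (0.20), AZL diverse (0.50), AZL2 intermediate
  (0.35) — with the catalytic window resampled from the subfamily pattern,
  a random 0–8 residue N-terminal extension, and rejection of accidental
  motifs outside the planted window by targeted replacement with residues
  that belong to no pattern class. The reference anchors are the synthetic
  base sequences themselves; no real protein sequences are shipped.
* Assay curves are generated from the fitted functional forms at the
  reported enzymology values (k = 7.8, 0.8, 0.04 min^-1; lag IC50 5.9 and
  3.9 uM; survival IC50 48.1 and 11.1 uM), with independent Gaussian noise
  per technical replicate and three replicates averaged per reported point,
  matching triplicate assay practice. Noisy fractions are not clipped to
  [0, 1]: clipping at the plateau would bias amplitude recovery, and real
  gel quantification also strays slightly outside the nominal range.

One master seed expands into per-entity child seeds through a fixed counter
scheme, so adding genomes or proteins never reshuffles existing ones and
all outputs are byte-identical for a fixed seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: nucleotide-level sequence content; phylogenetic
correlation between genomes (each genome is independent, so no clade
structure in the census); insertions/deletions within homolog proteins
(substitution-only divergence keeps window offsets exact); BGC prediction
error (intervals are taken as given, as they are downstream of a predictor
in real use); and annotation noise in product descriptions. Recovery of the
planted truth demonstrates internal consistency of the rules and fits, not
robustness to those real-data complications.

## Problem sizes

The default test and acceptance runs use 100 synthetic genomes
(~200 planted homologs, ~8,000 genes), 100-genome random layouts for the
exhaustive nearest-cluster cross-check, 200 seeded replicates for noisy
parameter-recovery coverage, and 8–9-point assay grids — sizes chosen to
exercise every rule at the scale the analysis targets while keeping a full
run in the minutes range on one core.

## Known limitations

* Window location assumes the query is alignable to an anchor; for
  proteins with no homology to either anchor, only scan mode applies, with
  its chance-match risk.
* The chi-square binning of distance distributions is a package choice;
  published P values from unknown binnings should be compared as bounds.
* The inside-cluster rule's gene-rank arm makes "inside" calls possible at
  large bp distances in gene-sparse regions; this is the rule as stated,
  not a bug.
* ANOVA on copy counts treats genomes as independent; no phylogenetic
  correction is attempted.
* Rates reported as lower bounds (plateau at the first time point) are not
  point estimates and should not be used in fold-change ratios.
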