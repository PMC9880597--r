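# scThalamus

Analysis toolkit for developmental single-cell RNA-seq of the embryonic
caudal diencephalon, where Sonic hedgehog (Shh) secreted from the zona
limitans intrathalamica patterns a rostro-caudal series of thalamic
progenitor domains. The package addresses a concrete analytical problem:
unsupervised clustering of thalamic progenitors is dominated by the cell
cycle, so progenitor subtypes have to be identified semi-supervised, from
panels of genes correlated with a handful of anchor markers (Nkx2-2,
Olig2, Dbx1, Rspo3), and the consequences of losing Shh signalling have
to be read out as changes in population *composition* between genotypes
rather than as cluster structure.

It is written for researchers analysing genotype-contrasted developmental
scRNA-seq time courses (control vs. Shh-pathway mutant, E12.5–E18.5) and
for methodologists who want the individual statistical components with
ground-truth simulations around them.

## What is implemented

* **QC** — barcode-rank knee detection on the log-log rank curve
  (rolling-median smoothing, uniform log-rank derivative grid, cliff
  depth/steepness confidence grading), UMI and mitochondrial-fraction
  filters with boundary-retaining semantics (cells with *fewer than*
  2,000 UMIs or *more than* 15% mitochondrial UMIs are removed),
  X/Y-gene removal, counts-per-thousand (CPT) normalisation, and
  clipped-standardised-variance selection of the top 2,000 variable
  genes.
* **Marker-anchored classification** — per-anchor top-k
  correlated/anti-correlated feature panels, correlation-distance
  average-linkage gene grouping, and per-cell assignment by
  size-normalised gene-set CPT totals with rostral-first tie-breaking.
* **Annotation transfer** — PCA representation (20 PCs of the variable
  genes), symmetrised kNN graph, seeded Louvain clustering, and the 2%
  cluster-composition rule: a cluster inherits every reference label
  carried by at least 2% of its cells.
* **Composition statistics** — two-sided Fisher's exact test by
  hypergeometric enumeration with the sample odds ratio
  `OR = (a·d)/(b·c)` oriented so `OR > 1` reads "depleted in mutants";
  BH adjustment; a rank-sum differential-expression screen with the
  `FC > 2, q < 0.05` decision rule and seeded subsampling of groups
  above 2,000 cells; expression-bin-matched cell-cycle scoring; Spearman
  correlation.
* **Shh response score** — the classic unweighted running-sum enrichment
  statistic (hits `+1/N_h`, misses `−1/(N−N_h)`, score = most extreme
  excursion, so `ES ∈ [−1, 1]`) of a fixed 9-gene Shh-responsive panel
  (Gli1, Ptch1, Olig2, Nkx2-2, Pdlim3, Fst, Zdbf2, Hs3st1, Slc38a11) on
  a fold-change-ranked gene list, with a seeded permutation p value.
* **Graph localization** — a degree-normalised Rayleigh quotient
  `Σ_{(i,j)∈E}(x_i−x_j)² / Σ_i d_i (x_i−x̄)²` scoring how spatially
  restricted a gene is on the cell-similarity graph, with a one-sided
  permutation test.
* **Synthetic data** — a negative-binomial generator with full ground
  truth: rostro-caudally graded progenitor domains with soft boundaries,
  a shared G2/M confound, bifurcating Sox2/Foxp2 lineages,
  genotype-specific domain depletion with a closed-form expected odds
  ratio, lognormal library sizes, mitochondrial genes, and an ambient
  barcode tail for knee QC.

## Worked example

Simulate the default genotype contrast (1,800 cells per genotype, five
domains, 10× mutant depletion of the two rostral domains), classify every
cell from the marker panel, and test per-domain composition:

```r
library(scThalamus)
spec  <- simulation_spec()                # study-condition defaults
pair  <- simulate_genotype_pair(spec)
labels <- assign_cells(normalize_cpt(pair$counts), default_feature_panel())
mean(labels$label == pair$truth$domain)
#> [1] 0.891
composition_enrichment(labels$label, pair$cells$genotype)
#>      label odds_ratio        p        q
#>    rTh.Pro      7.751 1.92e-67 9.61e-67
#>   cTh.Pro1      4.308 2.04e-41 5.11e-41
#>   preT.Pro      0.613 5.55e-07 5.55e-07
#>  epiTh.Pro      0.509 5.38e-17 6.73e-17
#>   cTh.Pro2      0.508 3.49e-22 5.81e-22
```

With 89% of cells classified correctly despite the soft domain
boundaries, the two Shh-dependent rostral domains show strong
control-enrichment (odds ratios 7.8 and 4.3, i.e. depletion in the
mutant), while the caudal domains are relatively over-represented in
mutants (odds ratios below 1) because composition is compositional — the
analytic odds ratio for the pooled rostral group is exactly 10 under the
generator (`analytic_odds_ratio(spec, c("rTh.Pro", "cTh.Pro1"))`).

The loss of the rostral domains also surfaces as a Shh response score:
ranking all genes by control-vs-mutant fold change and scoring the
9-gene panel gives

```r
de  <- de_rank_test(pair$counts,
                    pair$cells$barcode[pair$cells$genotype == "control"],
                    pair$cells$barcode[pair$cells$genotype == "mutant"])
shh_response_score(de[, c("gene", "log2fc")], seed = 0)
#> ES = 0.921, permutation p = 0.000999
```

A command-line wrapper over the same functions is installed at
`inst/scripts/scthalamus` (subcommands `simulate`, `qc`, `classify`,
`transfer`, `enrich`, `score`, `localize`), each writing TSV/JSON outputs
plus a JSON run report with the seed and configuration needed to
reproduce it.

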