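---
title: "Models and methods behind scThalamus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scThalamus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the design decisions taken where the
methodology was genuinely open. The companion README shows the worked
example; here we explain why each piece looks the way it does.

# The analytical setting

Thalamic progenitors in the embryonic caudal diencephalon are arranged in
rostro-caudal domains, each marked by an anchor transcription factor
(Nkx2-2 rostrally, then Olig2, Dbx1, Rspo3, Pax7). Two features of these
data shape the whole pipeline:

1. **The cell cycle dominates unsupervised structure.** Progenitors are
   proliferating; the shared S/G2/M program out-weighs the subtype
   signal, so clustering on variable genes groups cells by phase rather
   than identity. The package therefore classifies progenitors
   *semi-supervised*: gene panels are built by correlation with the
   anchors, and cells are assigned by their summed expression over each
   panel subset.
2. **Genotype effects are compositional.** Removing Shh signalling does
   not create new transcriptional states so much as it changes how many
   cells occupy each state. The genotype contrast is therefore a
   population-by-genotype contingency problem (Fisher odds ratios), plus
   a gene-set score of how Shh-responsive genes move in a fold-change
   ranking.

# The generative model of the simulator

`simulation_spec()` fully describes a synthetic dataset; every stochastic
draw is pinned by `rng_seed`, so a spec plus a seed reproduces the counts
bit for bit.

* **Domains.** The unit axis is split into segments at the midpoints
  between domain positions. A cell samples a domain (by `weights`,
  default `0.2/0.2/0.3/0.2/0.1` across five domains), then a uniform
  position within its segment. Each domain's genes (its anchor plus
  eight markers) have expected expression
  `mu_low + (mu_high − mu_low) · prox`, where `prox = 2/(1 + exp(d/s))`
  decays with the distance `d` from the domain segment and softness `s`
  (`boundary_softness`, default 0.05 axis units). At `s = 0` the kernel
  is a hard indicator, so a cell expresses exactly one domain's genes —
  the regime in which classification should be essentially perfect. At
  positive softness, cells near a boundary co-express the two flanking
  domains' markers, which is the biologically realistic regime and the
  reason default classification accuracy sits near 0.9 rather than 1.
* **Counts.** Expected expression is built on the counts-per-thousand
  (CPT) scale, rescaled per cell so the expected total equals a
  lognormal library size (`meanlog = log(4891)`, `sdlog = 0.39`, chosen
  to reproduce a realistic per-cell UMI median near 4,900 with a
  plausible interquartile spread), and sampled as negative binomial with
  one shared dispersion `theta = 2` (variance `mu + mu²/theta`), the
  simplest model matching 10x-style overdispersion.
* **Housekeeping, mitochondria, cell cycle.** Forty housekeeping genes
  carry a fixed log-spaced CPT ladder; ten `mt-` genes are assigned
  whatever mean gives an expected mitochondrial share of 2.7% of the
  library; a 15-gene G2/M program sits at baseline 1 CPT and gains an
  additive 10 CPT in a `cycling_frac = 0.3` subset of cells. The cycle
  is an additive program rather than a latent-phase model — enough to
  create the confound the scoring and regression machinery must handle,
  without claiming to emulate cycle kinetics.
* **Genotype depletion.** Mutant cells sample domains with weights
  `w_d · depletion_d`, renormalised. The implied population odds ratio
  for any domain group has the closed form
  `OR = [p_c/(1−p_c)]/[p_m/(1−p_m)]` and is exposed as
  `analytic_odds_ratio()`; at the defaults (10× depletion of the two
  rostral domains) it is exactly 10. The 9-gene Shh-responsive panel is
  deliberately placed among the rostral domains' markers, so genotype
  depletion propagates to the fold-change ranking that the enrichment
  score reads — mirroring the biology in which the Shh-proximal domains
  are the Shh-responsive ones.
* **Lineage.** `simulate_lineage()` draws pseudotime `t ~ U(0,1)` and a
  branch (A/B); a shared progenitor program decays linearly in `t`, each
  branch's marker (Sox2 / Foxp2 by default) rises linearly on its own
  branch only, and expression responds to `t` plus Gaussian noise
  (`pt_noise = 0.1`, truncated to `[0,1]`) while truth records the clean
  `t`. Among late cells this yields the anti-correlated,
  mutually-exclusive marker structure of two diverging neuronal
  lineages.
* **Ambient tail.** `simulate_barcode_ranks()` adds geometric-tailed NB
  pseudo-barcodes (5,000 at mean 50 UMIs by default) under the real
  cells' lognormal library sizes, producing the bimodal log-log rank
  curve whose knee the QC module must find.

**What the simulator does not emulate** — batch effects between
libraries, ambient RNA contamination *within* real cells, doublets, gene
length/GC biases, and splicing dynamics. Tests passing on these
simulations therefore demonstrate the statistical machinery under its
stated assumptions, not robustness to those artefacts; on real data,
batch correction (e.g. Harmony) would have to sit between normalisation
and the PCA representation, and is intentionally outside this package.

# Quality control

* **Boundary semantics.** Filtering removes cells with *strictly fewer*
  than `min_umis = 2000` UMIs or *strictly more* than
  `max_mito_frac = 15%` mitochondrial UMIs, so cells at exactly 2,000
  UMIs or exactly 15% are retained. Mitochondrial genes are recognised
  by the case-insensitive `mt-` prefix (mouse convention) with an
  explicit override list.
* **Knee detection.** The barcode-rank curve is monotone by
  construction, so the signal is its shape, not noise. The detector (a)
  thins the sorted curve to the first and last rank of each distinct
  count, so integer plateaus become single steps; (b) applies a
  rolling-median of window 15 points; (c) interpolates onto a uniform
  grid of 256 points in `log10(rank)` and takes centred finite
  differences there — on the raw per-rank spacing, the deep tail's tiny
  `Δlog10(rank)` dominates every derivative; (d) places the knee at the
  most negative derivative. Confidence grading is the part that rejects
  look-alikes: a knee must be a dip the derivative *climbs back out of*
  (some later stretch at least 3× flatter), with a cliff of depth at
  least 0.5 decades falling at an average slope steeper than −10; a dip
  that recovers but fails the depth/steepness bar is reported `"low"`
  (a strictly geometric curve lands here) and a curve with no recovery
  — a single lognormal population, or ambient at the real cells' scale —
  is `"none"`. Whenever confidence is not high, the suggested threshold
  falls back to the configured `min_umis`, which is also why the
  pipeline carries a global UMI cutoff alongside the per-sample knee
  suggestion. The whole construction is scale-equivariant: multiplying
  all counts by `c` multiplies the threshold by `c`.
* **Variable genes.** Per-gene variance is standardised against a loess
  trend of `log10(var)` on `log10(mean)` (span 0.5, degree 2),
  per-cell values are clipped at `sqrt(n_cells)`, and genes are ranked
  by the variance of the clipped standardised values, ties broken by
  symbol. Constant genes score zero and can never displace a varying
  gene.

# Classification

* **Correlation measure.** Pearson on log1p-CPT, the representation the
  rest of the pipeline uses. Each anchor correlates perfectly with
  itself and so leads its own positive list; `include_anchors = FALSE`
  is available since a panel-size bookkeeping convention either way is
  defensible.
* **Score normalisation.** Cell scores are gene-set CPT totals divided
  by set size. Raw totals (`normalize = FALSE`) are also available, but
  unnormalised sums bias assignment toward large sets, so the
  size-normalised form is the default.
* **Ties and degenerate cells.** Exact score ties go to the most rostral
  label in `subpop_order` and are flagged; cells with zero score on
  every set are `"unassigned"` rather than forced into a domain.
* **Gene grouping.** Average-linkage clustering under `1 − r` distance,
  genes sorted lexicographically beforehand so `hclust` tie-breaking is
  order-independent; constant genes (undefined correlation) are dropped
  with a warning. The mapping from gene groups to subpopulation names is
  supplied by the user (the package suggests `default_feature_panel()`
  for the simulator's domains): naming populations is a judgement call
  on known markers that the package should not guess.

# Clustering and label transfer

The representation is the top 20 principal components of the centred,
scaled log-CPT matrix over the top 2,000 variable genes. The kNN graph
(`k = 15`, Euclidean, ties at the k-th neighbour broken by cell index) is
symmetrised, and Louvain maximises modularity at `resolution = 1` with a
pinned seed. Cluster counts are resolution-dependent and are treated as
such — nothing downstream assumes a particular number of clusters.
A cluster inherits every reference label covering at least
`min_label_frac = 2%` of its cells; multi-label clusters keep the whole
label set rather than being forced to one identity, and downstream
composition tests take an explicit label-selection rule instead.

# Statistics

* **Fisher's exact test** enumerates the hypergeometric support directly
  and sums the probabilities of all tables no more probable than the
  observed one (with a `1e-7` relative tolerance for floating-point
  ties). The reported odds ratio is the *sample* odds ratio
  `(a·d)/(b·c)` — not the conditional MLE that `fisher.test()` reports —
  with `x/0 = Inf` and `0/0` undefined. Orientation is fixed with
  control in the first column and the population of interest in the
  first row, so odds ratios above 1 always read "depleted in the
  mutant".
* **The DE screen** is a per-gene two-sided Wilcoxon rank-sum test on
  CPT (exact enumeration for tie-free groups of at most 50, otherwise
  the normal approximation with tie and continuity correction), with
  fold change computed on group mean CPT plus a pseudocount of 1 CPT,
  and the decision rule `|FC| > 2` and BH-adjusted `p < 0.05`. Groups
  above `de_subsample = 2000` cells are downsampled with a seeded draw.
  A rank test makes no distributional claim and calibrates cleanly on NB
  null data (measured type-I error ~0.05 at nominal 0.05); studies
  wanting a parametric NB GLM can compute per-gene fold changes and p
  values externally and feed the resulting table straight into
  `shh_response_score()` and the `FC/q` decision rule.
* **Multiple testing** is Benjamini–Hochberg throughout.
* **The enrichment score** is the classic unweighted running-sum
  statistic; the fold-change-magnitude-weighted variant changes the
  score's range and was not adopted because the unweighted form has the
  clean `[−1, 1]` extremes used as anchors in testing. The p value
  permutes gene-set membership (1,000 seeded draws by default) and is
  one-sided in the enrichment direction, `(1 + #{ES_perm ≥ ES}) /
  (n_perm + 1)` — uniform under the null by exchangeability.
* **Cell-cycle scores** subtract the mean of a control set drawn from
  expression-matched bins (25 bins, 50 controls per set gene, seeded),
  so library-size and depth effects cancel; phase is the argmax of
  (S, G2M) when positive, else G1.

# Graph localization

The score of a signal `x` on the cell graph is the degree-normalised
Rayleigh quotient `Σ_edges (x_i − x_j)² / Σ_i d_i (x_i − x̄)²`: low when
`x` varies between, not within, neighbourhoods. This is deliberately the
1-skeleton (plain graph) case of spectral localization — the
simplicial-complex generalisation with higher combinatorial Laplacians
adds machinery that the localization use-case here (finding genes that
mark sub-populations clustering cannot separate) does not need. The test
is one-sided toward low scores with seeded vertex permutations, scored in
bulk as matrix operations. On a disconnected graph the signal is centred
within each component (with a warning), so a constant offset between
components does not masquerade as localization. Note the permutation
granularity: with `n_perm` permutations the smallest attainable p is
`1/(n_perm + 1)`, so BH-significance across many candidates requires
`n_perm` comfortably above `n_candidates / alpha`.

# Problem sizes and numerical conventions

The bundled tests and the acceptance script run the generator at the
default study conditions where the quantity under test needs them (1,800
cells per genotype for composition; 200 replicate seeds for the
odds-ratio sampling distribution; 2,000 null genes for DE calibration;
500 real cells plus 5,000 ambient barcodes for knee recovery) and at a
few hundred cells where only correctness of bookkeeping is at stake.
Medians use the midpoint convention for even counts. Duplicate gene
symbols are deduplicated deterministically (`.1`, `.2`, … in file order);
merged barcodes are suffixed `-<sample_id>`. All matrices are gene-by-cell
and sparse; densification happens only inside per-operation working sets.

# Known limitations

* No batch integration: cross-sample structure is assumed biological.
* The rank-sum DE screen trades power for calibration relative to an NB
  GLM; very low-count genes lose the most.
* The knee detector assumes a raw-like barcode distribution; on
  pre-filtered (cell-called) matrices there is no ambient tail and it
  will correctly report no knee, leaving the global UMI cutoff in
  charge.
* Simulated domains share one dispersion and one boundary softness;
  real domain boundaries are unlikely to be homogeneous, and no
  quantitative calibration of softness to tissue is implied.
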