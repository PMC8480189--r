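---
title: "Detecting and karyotyping inversions under parallel adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and karyotyping inversions under parallel adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parinv)
```

# The study design

`parinv` targets a recurring design in adaptation genomics: one
ancestral population (here, an anadromous ecotype) and several derived
populations (freshwater-resident ecotypes) that were founded
independently and recently. Under this design, three genomic signatures
separate parallel selection from drift and geography:

* the **same alleles** rise in frequency in *every* derived population,
* those alleles segregate at low frequency in the ancestral population
  (selection from **standing variation** rather than new mutation), and
* when the selected haplotype is held together by a **chromosomal
  inversion**, the region shows a block of extreme linkage
  disequilibrium, elevated FST, and a three-cluster genotype structure
  corresponding to the AA/AB/BB karyotypes.

The package implements each link of that chain and a simulator that
generates the whole design with ground truth, which both the examples
below and the test suite use.

```{r}
sim <- simulate_genotypes(sim_config(seed = 7))
dataset <- apply_filters(sim$dataset, filter_config())$dataset
dataset
```

# Filtering

`apply_filters()` first masks individual genotypes with depth below
`min_depth` or genotype quality below `min_genotype_quality`, then
removes sites by the first failed criterion in a fixed order: per
population call rate, site quality, per-population observed
heterozygosity (excess heterozygosity flags paralogous collapse), and
global minor allele frequency. A site failing the global MAF threshold
is *rescued* when some population carries it at a local MAF of at least
`rescue_local_maf` — a locally common allele in one founded population
is exactly the kind of variant the scan must not discard. Each removal
is attributed to the criterion that first failed, so the filter report
sums to an exact account of the input.

# Dual outlier scan

Two scans with different failure modes are intersected:

* **Exact allele-count test.** For each ancestral–derived pair, a
  two-sided Fisher exact test on the 2×2 allele-count table
  (`fet_exact_p()`); two-sided mass is accumulated over all tables with
  probability at most that of the observed table, with a small relative
  tie guard so equal-probability tables are included.
* **PCA outlier scan.** `pca_outlier_scan()` regresses dosages on the
  leading principal components, forms robust Mahalanobis distances of
  the loadings (MASS's minimum covariance determinant), rescales by the
  genomic inflation factor (median χ² rule), and converts to q-values by
  Benjamini–Hochberg.

A SNP becomes a candidate only if **both** methods flag it in **every**
ancestral–derived pair. This all-pairs intersection is what encodes
parallelism: a locus divergent in only some populations — however
strongly — is not a candidate. `assign_fwa()` then gives each candidate
its freshwater-favored allele only when that allele's frequency rises
in all derived populations, recording the per-population increments and
whether the allele was already segregating ancestrally (standing
variation).

# LD-network clustering

LD is computed on **pooled** populations (`ld_r2()`): pooling creates
admixture LD between any loci differentiated along the same population
axis, and this is deliberate — it is what makes a diverged inversion
visible as a dense LD cluster even though recombination within each
arrangement class is normal.

`build_merger_tree()` descends an r² threshold grid. At each level the
connected components of the graph with edges r² ≥ threshold are formed;
all edges belonging to one level are applied together, so a component is
never grown one chance edge at a time within a level. When components
merge, each pre-merge component is recorded with

λ = n_loci × (median r² within before − median r² within after),

where unstored pairs count as zero in the medians. λ is large when a
tight cluster (median r² ≈ 1) is absorbed into a loose background —
the signature of a discrete rearrangement, not of smooth isolation by
distance. Components still separate after the grid are merged into a
chromosome root at threshold zero so every cluster's λ is defined.

Among clusters with at least `E_min` edges, outliers satisfy
λ > median(λ) + φ·MAD(λ). The stringency φ is selected by
`select_phi()`: starting at 2 it is incremented until the extracted set
is unchanged for three consecutive increments. An outlier cluster
containing no other extracted outlier cluster is a **single-outlier
cluster (SOC)** — the inversion candidate; clusters that contain one
are compound (COC).

## Trimming admixture-linked loci

A single-linkage component admits a locus on the strength of a single
edge. Two contaminant classes matter here: loci tied to the cluster by
one chance pairing, and — more insidiously — loci that are strongly
ecotype-differentiated (for example, independently selected loci
elsewhere in the genome) whose pooled-LD to every inversion member is
moderate *admixture* LD, not physical linkage. Pooled r² cannot
separate the latter from true members, but within-population LD can: a
genuine member of a recombination-suppressed rearrangement remains
correlated with other members *inside* each population, because the two
arrangement haplotype pools segregate within populations, whereas
admixture LD vanishes once population means are removed.

`soc_postfilter()` therefore applies the cluster retention gate
member-wise in structure-corrected form: each member must have median
within-population r² (`within_pop_r2()`) to the other members of at
least `min_median_r2`, iterated to a fixed point
(`trim_bridge_loci()`). Cluster statistics and span are recomputed on
the trimmed set; λ is kept as extracted since it scores the merger
event. Surviving SOCs must still have ≥ `min_cluster_loci` members and
median pooled r² ≥ `min_median_r2`.

`soc_span()` reports the raw span and an adjusted span in which any
internal member-free interval of at least `min_gap_bp` whose flanking
member groups remain in high LD across the gap (median cross-gap r² ≥
`min_cross_gap_r2`) is subtracted as an assembly artifact; a gap with
low cross-gap LD is genuine extent and is kept.

# Karyotyping

`region_pca()` decomposes the mean-imputed, centered genotype submatrix
of the SOC members. For an inversion, PC1 separates three groups —
the two homokaryotypes with heterokaryotypes between them. The PC1 sign
is fixed so the ancestral-population mean is negative, making the
orientation reproducible across runs.

Grouping on PC1 uses `kmeans_1d()`, an exact dynamic program over the
sorted values (optimal 1-D clusters are contiguous), so the partition is
deterministic and provably optimal — no random restarts, no seed.

`assign_karyotypes()` labels the extreme group holding the majority of
ancestral individuals AA, the middle group AB, the other extreme BB,
and then checks two validity gates that are *reported, never silently
repaired*: the ancestral majority must fall in an extreme group, and
the AB group must have the strictly highest mean heterozygosity across
the region (heterokaryotypes carry one copy of each arrangement, so
every arrangement-differentiated site is heterozygous).
`karyotype_frequencies()` converts assignments to per-population
karyotype and arrangement-allele frequencies with
freq_B = (n_AB + 2·n_BB) / 2N.

Finally `classify_soc_cause()` reads the frequency table: a shift of at
least `delta` (default 0.5), with the same sign, in every derived
population relative to the ancestral mean is **parallel adaptation**; a
split of at least `delta` among the derived populations without a
uniform shift is **geographic structure**; anything else is
unresolved. `inversion_fst()` supplies the accompanying FST contrast of
the SOC region against the LD-pruned neutral set.

```{r}
ldn <- ld_network_scan(dataset)
soc <- ldn$socs[1, , drop = FALSE]
karyo <- karyotype_soc(dataset, soc)
karyo$frequencies[, c("population", "nAA", "nAB", "nBB", "freq_B")]
karyo$cause
```

# Conventions worth knowing

* **Expected heterozygosity** uses the small-sample unbiased form
  2p(1−p)·2n/(2n−1) over called genotypes.
* **Weir–Cockerham θ** is the two-population ratio-of-sums multi-locus
  estimator; monomorphic-in-both loci contribute nothing. Permutation
  significance shuffles individuals between the two populations;
  adjusted p-values across pairs use Benjamini–Yekutieli.
* **`neighbor_coverage()`** counts a SNP as covered within distance `d`
  on the same chromosome, inclusive of endpoints, merging overlapping
  intervals; single-SNP chromosomes are excluded from the
  nearest-neighbor fraction (they have no neighbor to measure).
* **Problem sizes** are package choices, not constraints: the defaults
  (5 populations × 22 samples, ~5,400 SNPs, one 20-Mb inversion) run
  the whole pipeline in well under a minute, and every stage accepts
  arbitrary numbers of chromosomes, populations and loci consistent
  with its documented inputs.
* **Determinism**: every stochastic component (simulation, permutation
  tests) takes an explicit seed and restores the caller's RNG state.
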