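---
title: "Linking gut metagenome, intestinal transcriptome and fat deposition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gut metagenome, intestinal transcriptome and fat deposition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gutlink` implements a multi-omics association pipeline for a classic
divergent-selection design: two broiler lines (lean and fat) with ten
birds per line, each sampled in four intestinal compartments (duodenum,
jejunum, ileum, ceca) for shotgun metagenome and mRNA-seq profiling,
alongside abdominal-fat phenotypes (body weight BW, abdominal fat weight
AFW, abdominal fat percentage AFP = 100·AFW/(1000·BW)) and a panel of
serum biochemical indices. This vignette explains the models and
procedures, the tunable parameters, the synthetic-data generator that
serves as the test bed, and the numerical choices made where the design
was genuinely open.

## 1. Gene-catalog relative abundance

Quantification starts from mapped read counts per catalog gene. Genes
with fewer than two aligned reads in *every* sample are removed
(`filter_low_support_genes()`; the stricter remove-if-any-sample-low
reading is available via `rule = "any"`, but the permissive reading is
the default because it matches standard gene-catalog practice: one
well-covered sample is evidence the gene is real). The relative
abundance of gene *k* in a sample is its length-normalized count divided
by the sample total:

$$G_k = \frac{r_k / L_k}{\sum_i r_i / L_i}$$

so gene-level columns sum to one wherever any read maps. Taxonomic
abundances at each of the seven ranks are sums of member-gene
abundances, with genes lacking a lineage collected into an explicit
`unannotated` row so that per-sample conservation is testable.
Functional abundances (KEGG pathway, CAZy family, eggNOG OG) are also
member-gene sums, but a gene annotated to several categories contributes
its full abundance to each, so functional columns may exceed one — a
documented property, not an error.

Features enter differential testing only if they are present in every
sample of at least one line *and* their within-line mean relative
abundance exceeds 0.1% in at least one line
(`prevalence_abundance_filter()`). The same mean-based rule is used for
taxa and functional categories.

## 2. Community profile

Richness is the count of detected features and the Shannon index is
$-\sum p \ln p$ over renormalized nonzero proportions (natural log, the
ecology convention; the base is configurable). Two-group comparisons of
diversity and of functional categories use the Mann-Whitney U test:
exact by enumeration when the pooled sample is tie-free with at most 16
observations, otherwise the normal approximation with tie and continuity
corrections.

Supervised ordination uses PLS-DA (`plsda_fit()`): NIPALS partial least
squares against the one-hot class matrix with sequential deflation,
centring always and unit-variance scaling by default (the convention of
the standard multivariate toolchain; neither choice is dictated by the
design). Component count defaults to 2 and classification accuracy is
estimated by leave-one-out cross-validation of a nearest class-centroid
rule in score space. Sign indeterminacy is resolved by requiring each
X-loading vector to have a non-negative sum, making scores reproducible.

The Firmicutes/Bacteroidetes ratio is computed per sample from the
phylum-level matrix; a zero Bacteroidetes abundance yields an `Inf`
sentinel with a warning rather than an error.

## 3. Differential abundance (Metastats-style)

`metastats_permutation_test()` uses the two-sample Welch *t* statistic
on relative abundances with a label-permutation null, the approach of
the original Metastats method. When $\binom{n}{n_1} \le 200{,}000$ every
assignment is enumerated and the p-value is the exact fraction of
permuted $|t|$ at or above the observed one (the identity permutation
included, so p > 0 always); otherwise `n_perm` Monte-Carlo draws are
used with the +1/+1 estimator $p = (1 + \#\{|t^\ast| \ge |t|\})/(1 +
n_\mathrm{perm})$. The sparse-count Fisher branch of the original method
is not implemented: features sparse enough to need it are removed by the
prevalence screen. Benjamini-Hochberg q-values are appended (step-up,
via `stats::p.adjust`), and two significance tiers are reported, FDR <
0.05 and 0.05 ≤ FDR < 0.1, with the direction (which line the feature is
enriched in) taken from the group means.

Inside the full cascade the per-compartment Metastats call uses the
Monte-Carlo path with 5,000 permutations: the 10+10 design's
$\binom{20}{10} = 184{,}756$ exhaustive splits cost an order of
magnitude more time for a resolution the downstream FDR threshold does
not need, and 5,000 draws keep the smallest attainable q below 0.05
even when a single feature is truly differential.

## 4. Differential expression

The DE stage is a deliberately simplified negative-binomial Wald test in
the DESeq2 mould; numerical equality with DESeq2 is not promised, but
size factors agree up to a constant and fold changes correlate > 0.97 in
the cross-check tests.

* **Size factors** are median-of-ratios: the median over always-present
  genes of the count over its across-sample geometric mean, rescaled to
  geometric mean one; when no gene is present everywhere the geometric
  means fall back to positive counts only, with a warning.
* **Dispersions** are method-of-moments on normalized counts,
  $\alpha = (s^2 - \mu \cdot \overline{1/s_j})/\mu^2$ with pooled
  within-group variance, floored at $10^{-8}$, and by default shrunk
  with weight 0.5 toward a log-linear dispersion-mean trend.
* **Testing** fits, per gene, a log-link NB GLM with intercept and line
  coefficient (offset = log size factor) by iteratively reweighted least
  squares, vectorized across genes. The Wald statistic is referred to a
  *t* distribution with $n-2$ degrees of freedom rather than a normal:
  the plug-in dispersions are estimated from the same 20 samples, and
  the normal reference is visibly anticonservative there (null type-I
  ≈ 0.068 against ≈ 0.050 with the *t*), in the spirit of
  quasi-likelihood F/t-tests.
* **Sign convention** is lean vs fat throughout: positive log2FC means
  higher expression in the lean line.
* **DEG rule**: FDR < 0.05 and |log2FC| > 1.5, both strict. All-zero
  genes report NA and are excluded from the BH correction.

Pathway enrichment of DEGs is the upper-tail hypergeometric test
$P(X \ge k)$ with the compartment's tested genes as the population; the
Rich factor is $k/n$, the proportion of a pathway's annotated genes that
are differentially expressed. Significance defaults to raw p < 0.05
(BH q is reported alongside). qPCR validation support computes
$-\Delta\Delta C_t$ log2 fold changes and their Pearson correlation and
regression $R^2$ against the RNA-seq estimates.

## 5. The association cascade

The core analysis chains four screens within each compartment:

1. **AFRT selection.** Every serum index is tested (Pearson, two-sided)
   against AFW and AFP across the 20 birds; indices with p < 0.05
   against either are abdominal-fat relevant traits, with AFW and AFP
   kept as anchors.
2. **Modules.** Expression is size-factor normalized and
   log2-transformed; module construction uses the genes with the
   largest *excess* variance over the expected technical variance
   $(1/\mu + \alpha)/\ln^2 2$ (raw variance ranking favours low-count
   genes whose log-scale measurement noise is large), 750 by default.
   The unsigned adjacency $|{\rm cor}|^\beta$ uses the smallest
   soft-threshold power $\beta$ whose connectivity distribution reaches
   scale-free fit $R^2 \ge 0.8$ (candidates 4-12; powers below 4 are
   excluded because at 20 samples they leave chance correlations
   essentially unshrunk). The topological overlap matrix
   ${\rm TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij})/(\min(k_i,k_j) + 1 -
   a_{ij})$ feeds average-linkage clustering on $1-{\rm TOM}$. The tree
   is cut statically; because the TOM scale moves with $\beta$, the
   default height is chosen per dendrogram as the merge-height quantile
   that maximizes the number of clusters of at least `min_module_size`
   (30) genes. Clusters below the size floor are grey. Eigengenes are
   first principal components of the standardized module expression,
   sign-oriented to the module mean profile, and modules whose
   eigengenes correlate above 0.75 are merged. A final kME refinement
   assigns every gene to the module whose eigengene it matches best
   (grey below |kME| = 0.5) — the standard cleanup of weighted
   co-expression practice, without which chance inter-factor
   correlations at 20 samples fragment planted modules.
3. **Gene screen.** Modules whose eigengene correlates with any AFRT at
   p < 0.05 are kept; genes inside kept modules pass if their own
   expression does the same. Hub genes additionally have |kME| ≥ 0.8;
   the hub flag is reported but the cross-omic stage uses the full
   AFRT-correlated set, since the hub definition is a convention the
   source analyses never pin down.
4. **Microbe screen and links.** Species are screened by Spearman
   correlation against the AFRTs (p < 0.05) on the
   prevalence/abundance-filtered species matrix — the same analysis set
   used for differential testing. In the species-rich ceca the screen is
   restricted to Metastats-significant species. Finally, every
   (species, AFRT-correlated DEG) pair is tested by Spearman
   correlation, keeping records at p < 0.05 in the small intestine and
   p < 0.01 in the ceca; cross-omic p-values are used raw, matching the
   stated thresholds.

Correlation p-values throughout use the *t* approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, for Spearman computed on
mid-ranks; this keeps the Pearson and Spearman screens on one footing.

## 6. The synthetic-data generator

The generator (`simulate_study()`) reproduces the study's design shape —
2 lines × 10 birds × 4 compartments — at desk scale: 300 microbial
species × 20 catalog genes each, 5,000 host genes, 100,000 mapped
metagenome reads per sample. Its defaults are the study conditions the
pipeline is tested under.

**Phenotypes.** Per-trait line means and SDs are the study population's
values (SD = reported SE × √10). Within each line standardized traits
follow a one-factor model $z_t = c_t f + \sqrt{1 - c_t^2}\,e_t$ with $f$
the bird's latent adiposity factor anchored by AFW; AFP is always
computed from the sampled AFW and BW, never drawn. The planted AFRT
positives are the eight serum indices the screen is meant to recover,
given within-line couplings of |r| = 0.8 with signs matching the line
effects (LDL-C gets a weak −0.3 so the HDL-C/LDL-C ratio behaves).
A full trait correlation matrix can be supplied instead; a
non-positive-semi-definite request falls back to the nearest valid
correlation matrix with a note. One caveat the generator cannot remove:
because AFP variance is almost entirely between-line while CHO variance
is almost entirely within-line, the pooled AFP-CHO correlation is
capped near 0.5 whatever the within-line coupling, so CHO is selected in
only about half of replicates at n = 20 — a property of the population
parameters, not of the screen.

**Microbiome.** Species log-baselines are normal with SD 2.0 — a heavy
tail with a few dominant species, but not so extreme that the noise of
one dominant species becomes a global compositional factor; per-sample
log-noise shrinks smoothly for dominant taxa (abundance-dependent
stability). Only 18% of species are present in the small intestine
(cecal communities are far richer, matching the population's biology);
planted species are pinned at a moderate relative abundance in every
compartment they occupy, because a dominant planted species would drag
every other proportion through renormalization and smear its coupling
over the whole community. Line-differential species multiply their
abundance by $2^{\rm log2fc}$ in the fat line; phenotype-coupled species
add $\sigma(\beta_f f + \beta_a z_{\rm AFP})$ to their log abundance,
where $f$ is a shared latent factor and $z_{\rm AFP}$ the standardized
AFP. Proportions are renormalized and converted to gene counts by
multinomial sampling with weights proportional to species proportion ×
gene length; with equal genes per species the length normalization of
the abundance equation undoes the length bias exactly, so species
proportions are recovered in expectation. Lineages are
prefix-consistent seven-rank strings with Firmicutes and Bacteroidetes
always represented; 3% of genes are left taxonomically unannotated to
exercise the conservation bookkeeping.

**Expression.** Counts are negative-binomial with log-normal
dispersions (median 0.05), per-sample depth factors (log-SD 0.25), and
planted log2-scale structure: line shifts for DEGs, three co-expression
modules driven by latent factors (one coupled to the adiposity factor at
r = 0.7, two null), and microbe-gene links realized by loading the gene
on the same latent factor that perturbs its partner species. Link-gene
loadings are sign-aligned with their planted line effects so the factor
coupling reinforces rather than cancels the DEG signal. The
adiposity-coupled module uses a smaller amplitude (≈ 0.47 log2 units)
than the null modules: large enough to pass the variance filter and
cluster, small enough that the factor's line shift stays below the 1.5
log2FC DEG threshold for its member genes.

**What the generator does not emulate.** Real phylogenetic correlation
among species, read-level errors, assembly and annotation noise,
multi-factor confounding (age, cage, batch), and library-specific GC or
length biases are all absent. Passing recovery tests therefore shows the
pipeline's statistical machinery is sound under the declared model; it
does not certify performance on real sequencing data.

**Reproducibility.** All randomness flows from one master seed through
named substreams (`phenotypes`, `latents`, `microbiome`, `expression`),
so layers can be regenerated independently and identical seeds give
byte-identical datasets and pipeline outputs.

## 7. Problem sizes and known limitations

The test suite runs the full cascade at the generator's default scale
(5,000 host genes, 300 species, 20 birds) over 20 seeds, the module
recovery at 2,000 genes over 10 seeds, and the DE recovery at 5,000
genes over 10 seeds; the brute-force oracles (permutation enumeration,
BH step-up, exact Mann-Whitney, hypergeometric draws) run on instances
small enough to enumerate completely.

Known limitations worth naming. First, with ten or so mutually
correlated AFRTs and a raw per-trait p < 0.05 rule, null species pass
the microbe screen at well above 5% — and, having been selected for
chance correlation with adiposity-aligned traits, they then correlate
with line-separated DEGs far above the nominal rate. The network
report therefore contains a substantial admixture of such
selection-driven edges around the genuinely coupled pairs; a
BH-corrected screen would remove them, but the raw-threshold behaviour
is the procedure being modelled. Second, DEG status requires a strong
line separation, and any line-separated quantity correlates with any
other across a two-line design; microbe-gene edges should be read as
"consistent with coupling", not as evidence of interaction beyond the
line contrast. Third, at 20 samples the co-expression machinery is
near its working limit: chance correlations between independent latent
factors reach |r| ≈ 0.4, which is why the kME refinement pass and the
power floor exist.
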