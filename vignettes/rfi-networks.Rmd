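---
title: "Multi-tissue co-expression networks and feed-efficiency phenotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue co-expression networks and feed-efficiency phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfinet)
```

# The problem

Residual feed intake (RFI) is the difference between an animal's observed
dry-matter intake and the intake expected for its growth rate and body
size; low-RFI cattle convert feed more efficiently at the same level of
production. `rfinet` implements the analysis stack for a progeny-test
design: two sire groups divergent for RFI (labelled `low` and `high`),
eight steers per group, five tissues per steer (pituitary, skeletal
muscle, liver, visceral adipose, duodenum) profiled by bulk RNA-seq,
plus feedlot phenotypes (14-d body weights, daily intake, bunk-visit
events, carcass weights in air and water).

The pipeline answers three questions. Which genes are tissue specific
(TS) or differentially expressed (DE) between sire groups? Which
transcription factors (TFs) look like regulators of the DE/TS response
(regulatory impact factors, RIF)? And how do these genes organise into a
co-expression network (PCIT), summarised by hubs, node classes and
tissue composition?

# Expression processing

Samples with fewer than 10 million mapped reads are discarded
(`qc_samples()`; the boundary is inclusive, "less than 10 M" being the
exclusion rule). Expression is quantified as RPKM,
$\mathrm{RPKM}_{gs} = 10^9 c_{gs} / (L_g N_s)$ with $c$ the read count,
$L$ the gene length (bp) and $N$ the sample's total mapped reads (the
supplied totals if present, otherwise column sums; the source is
recorded).

A gene is *expressed* when its mean RPKM reaches 0.2 in at least one
tissue (inclusive boundary). Tissue summarisation uses the arithmetic
mean over the tissue's samples; per-sample testing is available via
`filter_expressed(by = "any_sample")` since the original convention is
not recoverable. A gene is *tissue specific* when one tissue holds at
least two thirds of the summed per-tissue means (`tissue_share()`,
`classify_tissue_specific()`; "at least" makes the boundary inclusive,
and shares of 2/3 or more are necessarily unique). Downstream modelling
uses $Y = \log_2(\mathrm{RPKM} + 0.2)$; the offset defaults to the
expressed threshold so that retained zero cells stay finite, and it is
recorded in the object.

# The crossed random-effects model

Log2 expression is modelled as

$$Y_{ijkl} = \mu + G_i + GT_{ij} + GA_{ik} + GS_{il} + e_{ijkl}$$

with independent random effects of gene ($G$), gene-by-tissue ($GT$),
gene-by-animal ($GA$) and gene-by-sire ($GS$), and i.i.d. residuals, for
$i$ genes, $j$ tissues, $k$ animals and $l$ sire groups. All five
variance components are estimated by REML.

**Implementation.** Every random factor is crossed with gene, so genes
are independent given the components, with one shared $m \times m$
covariance $V(\sigma^2) = \sigma^2_G J + \sigma^2_{GT} A_T +
\sigma^2_{GA} A_A + \sigma^2_{GS} A_S + \sigma^2_e I$ over the $m$
retained samples (the $A$'s are same-tissue / same-animal / same-sire
indicators). The restricted likelihood therefore factorises over genes
up to the single fixed effect $\mu$, and is maximised directly with
L-BFGS-B over the five components rather than by EM sweeps over
Henderson's mixed-model equations — the same estimator with far less
machinery. This requires a common sample set across genes (true for
count matrices; whole samples discarded by QC drop out of $V$ for every
gene alike). Gene-wise missing cells are not supported.

Components are bounded below by $10^{-8}\,\mathrm{var}(Y)$ rather than
exactly zero. The floor is statistically negligible but keeps the
gene-by-sire BLUP direction defined when $\hat\sigma^2_{GS}$ hits the
boundary; because the DE z-score below is invariant to the scale of
$\sigma^2_{GS}$, this preserves null calibration instead of collapsing
every contrast to zero. A constant input matrix short-circuits to exact
zeros. Convergence uses the optimizer's relative-tolerance criterion
(documented default $10^{-6}$); `solve_blups()` refuses non-converged
fits. On balanced designs the estimates agree with the closed-form
ANOVA (expected-mean-squares) estimator, which the tests use as an
independent oracle.

**DE calls.** BLUP solutions at the REML ratios give per-gene sire
contrasts $d_i = \widehat{GS}_{i,\mathrm{low}} -
\widehat{GS}_{i,\mathrm{high}}$. These are standardised across genes and
a gene is DE when $|z_i| \ge 2$ (two-sided: both up- and down-regulation
count). Note that a two-sided normal 2-SD tail is $\approx 4.55\%$, not
the $P<0.01$ sometimes attached to this rule; the rule is implemented
literally as 2 SD and the discrepancy is left as documentation. No
multiple-testing correction is applied, by design. Per-tissue log2 fold
changes (low minus high group means within tissue) accompany the calls
for reporting.

# Regulatory impact factors

For a target set (default: the union of DE and TS calls) with group
mean log2 expression $e1_i, e2_i$ and TF–target correlations $r1_{ij},
r2_{ij}$ computed within each sire group (tissues pooled; a per-tissue
mode would simply subset samples first):

$$PIF_i = \tfrac12 (e1_i + e2_i)(e1_i - e2_i)$$
$$RIF1_j = \tfrac{1}{n_t}\sum_i PIF_i\,(r1_{ij} - r2_{ij})^2, \qquad
  RIF2_j = \tfrac{1}{n_t}\sum_i \left[(e1_i r1_{ij})^2 - (e2_i r2_{ij})^2\right]$$

Raw scores are z-standardised across TFs; `select_tf()` keeps TFs with
$|z| \ge 2$ on either score *and* mean expression above the across-TF
median. The concrete RIF1/RIF2 forms are the canonical realisation of
"abundance × differential expression × differential co-expression"; the
functions are versioned so alternative realisations can be swapped in.

**Limitations worth knowing.** Two structural effects cap the 2-SD TF
cut. First, z-standardisation is self-inflating: the true hubs sit in
the SD they are measured against, so with $K$ hubs among $N$ TFs the
achievable z is bounded near $s/\sigma_0 \cdot (1-K/N) / \sqrt{1 +
(K/N)(s/\sigma_0)^2}$. Second, with tissue-specific targets in the set,
whole same-tissue blocks of abundant TS targets move together, giving
every TF a heavy-tailed RIF noise floor. In the synthetic default world
this caps planted-hub selection recall near 0.5; with the
tissue-specificity channel switched off (`ts_fraction = 0`, the classic
differential-wiring setting) recall at $z \ge 2$ is 0.8–1.0, which is
what the recovery tests assert.

# PCIT network inference

Nodes are the union of TS, DE, TF and SNP genes (SNP genes: genes
harbouring RFI-associated GWAS variants, an externally supplied flag).
Pearson correlations are computed across all retained samples, tissues
pooled.

For every trio $(x, y, z)$ the three first-order partial correlations
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$
are formed, and the local tolerance is the mean absolute ratio of
partial to direct correlation, skipping terms whose direct correlation
is below $10^{-12}$ in magnitude (a documented guard; partials with a
degenerate denominator are treated as 0 inside the kernel, while the
user-facing `partial_correlation()` raises an error). The edge $x$–$y$
is eliminated when $|r_{xy}| \le \varepsilon |r_{xz}|$ and $|r_{xy}| \le
\varepsilon |r_{yz}|$ for at least one $z$; never-eliminated pairs are
*significant*. The scan is a compiled $O(n^3)$ kernel with $O(n^2)$
memory; a pure-R triple loop serves as the test oracle, and with fewer
than three nodes every pair is vacuously significant.

**Edge acceptance.** Significant pairs are thresholded at 2 SD. Two
choices here deserve explanation because the obvious readings fail on
structured data:

* *Reference distribution.* Standardising over the significant pairs
  only is degenerate whenever PCIT's survivors are the strong tail of
  the correlation distribution: their mean and SD (e.g. 0.07 and 0.52
  in the default synthetic world) put the 2-SD band beyond $|r| = 1$
  and **nothing** is ever accepted. The default therefore standardises
  over all candidate pairs and applies the cut to the surviving ones
  (`standardize = "significant"` retains the literal alternative).
  Accepted edges remain a subset of PCIT-significant pairs either way.
* *Sidedness.* "Greater than two standard deviations from the mean" is
  implemented one-sided (upper tail) by default. Under a two-sided rule
  the acceptance band also captures strong *negative* correlations,
  which in a multi-tissue design are dominated by tissue-specific genes
  of different tissues anti-correlating; the within-tissue edge
  fraction then drops below 0.5, irreconcilable with the expected
  ">90% of edges within tissue" structure of pooled-tissue networks.
  `sided = "two"` is available.

The statistic is the raw correlation of surviving pairs by default;
`stat = "partial"` standardises the mean first-order partial
correlation instead (accumulated in the same kernel pass).

# Network summaries

`build_network()` carries non-exclusive class flags (a node may be DE,
TS and TF at once) and each node's *tissue of highest relative
expression* (the argmax of its tissue shares, defined for TS and non-TS
genes alike, used for colouring and for the tissue edge summary).
`degree_table()` ranks nodes by incident accepted edges with ties broken
by gene id; `tissue_edge_summary()` reports the within-tissue edge
fraction and the least-squares $R^2$ of per-tissue outgoing (inter-
tissue) edge counts on node counts; `extract_tf_subnetwork()` keeps
TF-incident edges and their endpoints. Hub recovery is asserted on the
TF subnetwork's top-50 degree list: in the full network the top degrees
belong to same-tissue TS cliques (as in real multi-tissue panels, where
most top-degree genes are tissue specific, not TFs), so regulators can
only be expected to dominate the TF-incident subgraph.

Over-representation uses the one-sided hypergeometric tail
($P(X \ge k)$, equivalent to one-sided Fisher), flagged at $P < 0.05$
with no multiplicity correction by default, matching the analysis it
re-implements. Exports: SIF, TSV (exact round-trip via
`read_network_tsv()`), GraphML with node attributes.

# Feedlot phenotypes

Per animal and feeding period: ADG is the least-squares slope of the
14-d body weights on days; MMW is (mean period weight)$^{0.75}$; RFI is
the residual of the intercept-containing OLS fit

$$\mathrm{DMI} = b_0 + b_1\,\mathrm{ADG} + b_2\,\mathrm{MMW} + \mathrm{RFI}$$

fit across all animals of the period (both sire groups together), so
RFI has mean 0.00 by construction and is orthogonal to ADG and MMW.
FCR is DMI/ADG (undefined and flagged at ADG 0 — note that a group mean
of per-animal ratios is not the ratio of group means). Carcass specific
gravity is $CW/(CW - CW_{H_2O})$, strictly above 1 for any submerged
weight loss and decreasing in carcass fat. Feeding behaviour summarises
bunk events into visits/d, min/visit (NA with no events) and min/d.
Group differences use Welch's t-test by default (the safest choice at
n = 8 per group; pooled-variance is an option) with identical-group
degeneracy mapped to $p = 1$.

**Power.** The two-group RNA-seq power calculation uses
$n = 2 (z_{1-\alpha/2} + z_{\mathrm{power}})^2 (1/\mu + CV^2) / \ln^2 \Delta$
with biological CV on the log scale and $1/\mu$ the technical (Poisson)
term, inverted for power at given $n$; "top genes by coverage" is the
high-depth regime $1/\mu \ll CV^2$. The simulation mode draws
negative-binomial counts (dispersion $CV^2$) and applies a Wald test on
log group means with delta-method variance $(1/\bar{x} + CV^2)/n$ per
group, using the known simulation dispersion — estimating dispersion is
deliberately out of scope, as the calculation assumes CV known. At
$n = 8$, $\Delta = 1.8$, $CV = 0.4$, $\alpha = 0.05$ and high depth both
routes give $\approx 83\text{–}84\%$ power, consistent with the claim
that this design provides 80% power.

# The synthetic world

`simulate_expression()` generates what the analysis assumes, with
planted ground truth. On the log2 scale, per gene and sample:
baseline $\sim N(3, 2^2)$; a tissue-share profile (planted TS genes get
a dominant share drawn uniform on $[2/3, 0.95]$, the rest split
Dirichlet(1); non-TS genes draw a symmetric Dirichlet with
concentration 10, i.e. across-tissue CV ≈ 30%); a gene-by-sire shift of
$\pm\log_2(1.8)/2$ for planted DE genes (the detectable fold change of
the power statement; 4% of genes, the observed DE proportion at scale);
gene-by-animal effects $N(0, 0.25^2)$; and latent hub factors. Expected
counts allocate a fixed library of 20 M reads proportional to
expression × length, and counts are drawn as a gamma-mixed Poisson at
fixed library size (gamma shape $1/CV^2$, $CV = 0.4$, the power
statement's biological CV): per-gene marginals are negative binomial to
a very good approximation while per-sample totals are exactly the
target depth, as in real sequencing where depth is set by the run, not
by the biology. $CV = 0$ degrades to conditional Poisson.

Hub regulons: 6 abundant TFs (drawn from the top 40% of TF baselines,
since a TF screen with an abundance filter can only discover abundant
hubs) each drive a 20-gene module. Up to half of a module are planted
DE genes sharing one fold-change sign (a differentially active
regulator moves its regulon coherently; with mixed signs the
PIF-weighted RIF1 sum cancels identically), the rest drawn from SNP,
then TS, then remaining non-TF genes. The factor is standard normal per
sample with loading $0.9(1 \pm 0.8)$ in the low/high group — an
essentially group-specific regulon, which is what "planted differential
wiring" must mean for a wiring-difference score to have signal. Sixty
of the eighty planted DE genes sit in regulons; the twenty
free-standing ones measure DE recall in the clean, power-calculation
setting.

`simulate_phenotypes()` draws growth lines (254 ± 15 kg starting
weight, ADG 1.71 ± 0.15 kg/d, weights every 14 d over 70 d, 3 kg
measurement noise), intake from $\mathrm{DMI} = -1.3 + 2.0\,
\mathrm{ADG} + 0.10\,\mathrm{MMW} + \text{sire shift} + N(0, 0.25^2)$
(coefficients chosen to reproduce a 9.55 kg DM/d mean intake at the
observed ADG and MMW means; planted RFI shift −0.6 kg DM/d, low −
high), Poisson bunk visits (57.7/d mean, −12.9 planted difference) with
gamma durations (1.87 min, +0.60 difference), and carcass weights
consistent with specific gravity 1.08 ± 0.002 (+0.0045 difference).
Trait anchors are the published feedlot means; variance magnitudes are
this package's choices, documented here, not study values.

**What a green test establishes — and what it does not.** The generator
emulates overdispersed counts, tissue structure, sire effects, animal
effects and regulon wiring. It does not emulate read-level artifacts
(mapping bias, positional coverage), gene-length-dependent dispersion,
isoform switching, correlated baseline co-expression beyond the planted
modules, or compositional effects beyond those induced by the fixed
library size (visible as a small panel-wide coupling when very few
genes are simulated). Recovery on this world validates the code paths
and the internal consistency of the rules; it cannot certify the
biology of any particular dataset.

Everything is seeded: one experiment seed derives fixed per-stage
sub-streams (structure, effects, counts; phenotypes use an offset
sub-seed), so identical configurations are bit-identical end to end.

# Numerical and degenerate-input conventions

* QC keeps totals exactly at the threshold; the expressed and TS rules
  are inclusive at 0.2 and 2/3.
* `log2_transform()` refuses offset 0 in the presence of zeros.
* Variance components: floor $10^{-8}\mathrm{var}(Y)$ (residual
  $10^{-6}$, keeping $V$ positive definite); constant input
  short-circuits; gene reordering cannot change estimates.
* `call_de()` warns and calls nothing at zero contrast SD; it requires
  at least 10 genes for the SD to mean anything.
* PCIT tolerance ratios skip near-zero direct correlations
  ($<10^{-12}$); degenerate conditioning inside the kernel yields a 0
  partial rather than an error; fewer than 2 surviving pairs (or zero
  SD of the reference statistic) accepts nothing, with a warning.
* Degree ties break by gene id, making every ranking reproducible.
* Welch's test maps identical groups to $p = 1$; FCR flags ADG 0 as NA;
  specific gravity requires $CW > CW_{H_2O}$.

# Known limitations

* The mixed model requires a complete genes × samples matrix (samples
  may be dropped, individual cells may not).
* RIF's 2-SD selection is conservative in worlds with strong
  tissue-block structure (see above); the scores themselves are still
  informative for ranking.
* The trio scan is exact $O(n^3)$; ~2,000 nodes is comfortable desk
  scale, far beyond that a blocked or approximate screen would be
  needed.
* Graph layout, community detection, pathway-activation scoring and
  GO-term retrieval are out of scope; exports carry the attributes that
  external tools need.
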