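---
title: "Annotation-guided genomic selection with annogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-guided genomic selection with annogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annogs)
```

# The problem and the model

Genomic selection predicts a quantitative phenotype from genome-wide SNP
dosages coded 0/1/2 (copies of the minor allele; 0 is the major-allele
homozygote). With whole-genome sequencing the marker count dwarfs the
population size, and most markers carry no signal for any given trait.
`annogs` addresses this by routing the genotype signal through a network
whose architecture encodes population-level functional annotation — no
individual-level omics measurements are needed.

Each internal layer computes `f(Wx + b)` (ReLU by default) with batch
normalization and dropout, and training minimizes

$$\mathrm{loss} = \frac{1}{n}\sum_i (y_i - \hat y_i)^2
  + 10^{-5}\,\alpha_k \sum_j |w_j|^k,$$

the mean squared error plus a *binding penalty*: the fixed coefficient
$10^{-5}$ times the regularizer rate $\alpha_k$ times the elementwise
$k$-norm power of all weight tensors ($k = 1$ for L1, $k = 2$ for L2). The
notation $\sum \lVert w \rVert_k$ is ambiguous in isolation; we read it as
$\sum_j |w_j|^k$ over every weight entry, the standard penalty, and test
that a zero penalty recovers the MSE to machine precision.

## Layer structure and masks

The internal layers are sized `base_unit * unit_ratio` (defaults 110 and
1:2:4:5:6:7, giving 110–770), followed by a width-1 output node. We
resolved an ambiguity in the layer accounting in favour of this reading:
the six ratio entries scale six internal trainable layers, and the output
affine map is separate. The first three internal layers carry biological
identities:

1. **element layer** — nodes are cis-regulatory elements (for noncoding
   SNPs) and per-coding-SNP RNA-structure units;
2. **gene layer** — nodes are genes;
3. **metaterm layer** — nodes are gene-module metaterms.

Connectivity masks zero out every weight not supported by the annotation
graph: a SNP connects only to its element's (or structure unit's) nodes,
an element node only to the genes within its cis window. Nodes are
allocated to entities round-robin, so each node maps to exactly one
entity. Two consequences matter in practice:

* a SNP with no element/gene assignment has **exactly** zero fan-out — its
  gradient on the output is identically zero (tested by finite
  differences), which is the formal sense in which the model ignores
  unannotated variation;
* when a layer's width is smaller than its entity count, the surplus
  entities receive no node and their SNPs are silenced. Widths should
  therefore be chosen at least as large as the entity counts they
  represent; the packaged defaults assume this and the simulated-cohort
  examples satisfy it. This is a real capacity limit of entity-mapped
  architectures, not an implementation detail.

## Annotation levels and injections

`annotation_level` selects nested model inputs: genotype only (1), plus
per-SNP allele-impact channels (2), plus gene-function term features (3),
plus metaterm module features (4). Injections are *fixed, non-trainable
feature maps* concatenated at the target layer's input:

* level ≥ 2: the genotype vector elementwise-scaled by the signed
  allele-impact delta (alternative minus reference accessibility for
  noncoding SNPs, normalized minimum-free-energy difference for coding
  SNPs), sharing the SNP masks;
* level ≥ 3: per-term features — impact-weighted gene burdens combined
  with the gene-by-term score matrix — masked so term *t* feeds only genes
  annotated to *t*;
* level 4: per-metaterm features from the term-by-metaterm weight matrix,
  masked one-to-one onto metaterm nodes.

Annotation is population-level, so a literal constant side-input could
never change per-individual predictions; realizing the injections as fixed
annotation-weighted transforms of the genotype keeps them non-trainable
while letting annotation genuinely inform prediction. The injected term
and metaterm features double as traceable nodes for interpretability.

## Training, the plateau rule, and prediction

Training is full-batch gradient descent with momentum (defaults: learning
rate 0.1 on the real-scale architecture; the desk-scale examples here use
0.01–0.05), batch-normalization running statistics accumulated with
`bn_momentum`, dropout active only during training. The recorded loss
trace is evaluated deterministically after each update (batch statistics,
dropout off), so a zero learning rate provably freezes the trace. The
optimal step count is the *first attainment of the global minimum* of the
trace — the step after which the loss never decreases again — and
`optimal_step()` implements exactly that rule. Prediction runs in
inference mode (running statistics, no dropout) and is deterministic and
row-order-equivariant.

Weight initialization is scaled-uniform on the masked connectivity;
optimizer family, activation and batch policy are explicit, configurable
arguments rather than hidden constants, and every seed used is an
argument.

# Baseline models

`gblup()` fits $y = \mu + g + \varepsilon$, $g \sim N(0, K\sigma_g^2)$,
with $K = ZZ'/p$ on column-standardized codes (centered by twice the
allele frequency and scaled by $\sqrt{2f(1-f)}$). The scaling keeps the
mean diagonal of $K$ near 1 so that $\sigma_g^2/(\sigma_g^2 +
\sigma_e^2)$ is heritability on the phenotypic scale; with raw centered
codes the ratio would be off by the mean column variance. REML uses the
eigendecomposition of $K$ with the residual variance profiled out;
negative components are clipped at zero and reported. Only an intercept is
fitted as a fixed effect, matching standard practice for these
models.

`rrblup()` is the marker-effect parameterization $y = \mu + Gu +
\varepsilon$ with ridge parameter $\lambda = \sigma_e^2/\sigma_u^2$ from
the same REML criterion and effects from the normal-equations solve
$(G'G + \lambda I)^{-1}G'(y-\hat\mu)$; its predictions equal GBLUP's to
numerical precision under the matched scaling $\sigma_u^2 = \sigma_g^2/p$,
and the test suite asserts the equivalence to $10^{-6}$ on random
instances. `multiblup()` gives each SNP class its own kernel and variance
component, estimated by bounded quasi-Newton maximization of the
restricted likelihood (tolerance $\sim 10^{-8}$); a single class reduces
it to GBLUP and the multi-kernel optimum can never fall below the nested
single-kernel one.

`bayesr()` is a Gibbs sampler for the 4-component normal-mixture prior on
SNP effects with variances $(0, 10^{-4}, 10^{-3}, 10^{-2})\,\sigma_g^2$
and Dirichlet(1,1,1,1) mixing proportions; components are sampled from
their exact conditionals with the effect marginalized, then the effect
from its conditional normal. The variance components carry
weakly-informative scaled-inverse-$\chi^2$ priors (df 4, scale half the
phenotypic variance each). `bayesrc()` gives each disjoint annotation
class its own proportions; with one class it reproduces the BayesR chain
bit-for-bit under the same seed, and an empty class's posterior equals the
prior. One behaviour of these priors is worth knowing: under a pure-noise
trait $\sigma_g^2$ collapses, the small/medium components become
indistinguishable from the point mass at zero, and the posterior
proportions spread across those near-null components rather than piling
onto the null alone. The identifiable signatures of a null trait — a
suppressed large component, negligible posterior effect mass — are what
the tests assert.

The disjoint classes follow the published 5-class scheme: nonsynonymous
SNPs inside conserved-region genes (I) or metaterm signature genes (II),
other SNPs within ±50 kb of those gene sets (III, IV), and everything else
(V), with precedence I > II > III > IV > V resolving overlaps; published
descriptions of the scheme leave the overlap rule unstated, and this
precedence is our one consistent choice. Windows extend from gene interval boundaries.

# Coordinates and formats

Interval files are BED-style 0-based half-open; SNP positions are 1-based.
Containment is evaluated as `start <= pos < end` directly on the stored
interval, so a SNP at the exclusive end coordinate is outside — the
boundary convention the interval-assignment contracts specify, applied
uniformly to element assignment, gene windows and class building, and
cross-checked against brute-force scans. VCF input is restricted to
complete biallelic SNPs: missing genotypes are a load error (imputation
belongs upstream), and codes are oriented so 0 is the cohort's
major-allele homozygote, ties broken toward REF.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: it builds
a genome layout (genes, cis-regulatory elements within ±1 Mb of host
genes), an annotation graph (low-rank-plus-noise gene-by-term scores,
disjoint-ish metaterm signatures, conserved/signature gene flags),
allele-impact scores, genotypes, and a phenotype with a known causal
cascade. Key defaults and their reasoning:

* 1,700 samples (a typical training cohort for this design); MAFs uniform
  on (0.05, 0.5]; genotypes Binomial(2, MAF) in linkage equilibrium, with
  an optional AR(1) Gaussian-copula block-LD mode because LD is the main
  acknowledged gap of the design.
* causal noncoding SNPs sit inside elements linked to the signature genes
  of one designated causal metaterm; causal coding SNPs sit inside those
  genes — so the causal signal genuinely flows through the annotation
  graph, which is what makes level-ordering and backward-tracing tests
  meaningful.
* causal SNPs get large allele-impact deltas (|Δ| ≈ 0.3–0.5, the better
  allele inside an accessibility peak at threshold 0.147); non-causal
  deltas are near-zero Gaussian (the distributional form is unstated
  upstream; near-zero Gaussian is our choice).
* additive effects are proportional to the impact delta, with magnitude
  multipliers following the small/medium/large mixture-scale convention;
  an `interaction_fraction` of causal pairs within the causal metaterm can
  receive products of centered dosages as epistatic terms.
* environmental noise is scaled so realized Var(genetic)/Var(total) hits
  `heritability_target` on the drawn sample; `heritability_target = 0` is
  allowed as a pure-noise boundary case with all effects exactly zero.

What it does **not** emulate: realistic LD beyond the block copula,
demography, allele-frequency/effect-size coupling, dominance, genotyping
error, or the scale of real sequencing panels. Passing tests on these
cohorts show the machinery is correct and the statistics calibrated; they
do not certify real-data accuracy levels.

# Hyperparameter voting

`evaluate_candidates()` scores randomly sampled hyperparameter
combinations by 2-fold cross-validated Pearson correlation at each
annotation level; `select_by_vote()` aggregates *marginally* — the score
of a value is the mean (or median) over all candidates carrying it — picks
the best value per (level, statistic) pair, and counts the 8 selections as
votes. Several aggregation units could define a value's score; marginal
aggregation over candidates is the one that reproduces the standard
8-selection voting arithmetic. All levels see the same candidate pool so votes are
comparable. Ties are broken toward the higher overall average PCC, and a
residual tie falls back deterministically to the first value in sorted
order. Degenerate candidates (divergence, constant predictions) are
recorded as missing and excluded from aggregation rather than zeroed.

# Evaluation statistics

`pcc()` computes pooled ("together") or per-fold ("separate")
correlations — the two genuinely differ when fold means are anti-aligned,
and a constructed 4-point case in the tests demonstrates it.
`relative_efficiency()` implements

$$RE(k) = \frac{\bar y_{\alpha'} - \bar y_{\mathrm{test}}}
               {\bar y_{\alpha} - \bar y_{\mathrm{test}}},$$

the realized genetic gain of selecting the top *k* by prediction relative
to selecting by observation. It is 1 at perfect ranking, can be negative,
averages to ~0 under random ranking, and is invariant to positive affine
transformations of the predictions. Ties break by stable sample order;
fractional top-percent counts floor with a minimum of 1; a `minimize`
switch handles traits improved by lower values (e.g. back-fat thickness).
Undefined statistics (zero-variance inputs, zero denominators) propagate
as `NA`, never as 0. `heritability_of_subset()` restricts the GRM to a SNP
set and reports the REML heritability — the measure used to ask how much
genetic variance a set of nominated causal variants explains.

# Interpretability

`extract_node_weights()` scores each node by the sum of absolute outgoing
weights in each CV-replicate model (the direction — outgoing — and the
statistic are choices we document; a max-based statistic is available),
ranks nodes per replicate and normalizes to (0, 1]. `rho_score()` is the
beta order-statistic aggregate with the ×m Bonferroni correction;
`aggregate_layer()` applies Benjamini–Hochberg across a layer's nodes.
The number of replicates equals the CV fold count, and weights are read
from each fold's trained model. Under a permutation null the pipeline's
false-discovery fraction stays below the nominal level (the rho p value is
conservative, so the empirical rate sits well under α).
`prioritize_cis_snps()` filters candidate noncoding SNPs by cis distance
(boundary distance ≤ 1 Mb, inclusive), SNP-layer adjusted p, and the
accessibility peak threshold — a SNP whose two allele scores both miss the
peak threshold is excluded no matter how significant its node is.

# Problem sizes, numerical choices, limitations

The examples, tests and the acceptance script run at desk scale: cohorts
of 300–2,000 individuals and 100–700 SNPs, network widths around 100,
Gibbs chains of 1,500–10,000 iterations, REML on eigendecompositions up to
n = 2,000. These sizes were chosen so that each documented property is
measurable in minutes on one CPU; the architecture itself scales with
layer widths and SNP count.

Numerical notes: REML tolerance ~1e-8 on the log-likelihood and variance
ratios clipped at zero; batch-norm epsilon 1e-5; dropout uses inverted
scaling; monomorphic SNPs contribute zero GRM columns; Henderson-solve,
normal-equation, quadrature and brute-force oracles back the main solvers
in the test suite.

Known limitations: (i) the level-4 over level-1 advantage, while present
in the median over replicate cohorts in the p ≫ n regime, is small at desk
scale and varies between seed sets — annotation helps most when markers
vastly outnumber samples, and small cohorts can flip individual
comparisons; (ii) entity-mapped layers need widths matched to entity
counts (above); (iii) LD-aware fine-mapping is out of scope — backward
tracing nominates, it does not adjust for linkage; (iv) deep
configurations with high learning rates can diverge, which training
reports as an explicit error naming the step rather than silently
continuing.
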