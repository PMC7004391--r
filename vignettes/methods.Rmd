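---
title: "Models and methods behind sexbiasnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexbiasnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sexbiasnet analyses sex-biased gene regulation across a developmental
transcriptome time series: five ordered stages (early embryo, late embryo,
larva, pupa, adult), two sexes, three biological replicates per cell, with
optional testis and ovary samples matched to the male-pupa and adult-female
cells. This vignette explains the statistical models the package
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## From exons to nodes

The input is an exon-by-sample matrix of log2 expression (array-style
log-ratios over a noise floor). Preprocessing has three steps.

**Flooring and detection.** `apply_expression_floor()` sets every value
strictly below the experiment-wide 66th percentile to zero. The cut is
quantile-definition-sensitive, so the definition is fixed: the
inverted-ECDF quantile (type 1), whose threshold is always an observed
value; values equal to the threshold survive. `filter_detected()` then
keeps exons with positive signal in at least two replicates of at least one
stage-by-sex-by-tissue cell.

**Node decomposition.** `decompose_nodes()` separates whole-gene
transcription from isoform switching. Constitutive exons (present in every
isoform) carry the gene's transcription signal; their mean log2 value is
the gene's *transcription node*. Each group of facultative exons that share
an isoform-presence pattern becomes a *splicing node* whose value is the
splicing ratio: the group's mean linear signal divided by the gene's mean
constitutive linear signal, clamped to [0, 1]. Ratios estimate the fraction
of the gene's transcripts carrying the exon group and are decorrelated from
overall transcription level. The mean (rather than sum) aggregator makes
the ratio insensitive to how many exons annotate each side. Samples where
the gene total is zero get ratio 0, and a floored (zero) log2 value is
treated as zero linear signal.

**CCRE collapsing.** `collapse_ccres()` groups nodes whose pairwise Pearson
correlation exceeds 0.95 into Constitutively Correlated Regulatory Events
and keeps one representative per group (most above-threshold links within
the group; for pairs, the higher mean). Grouping is by connected components
of the above-threshold graph by default — the single-linkage behaviour of
standard row-collapsing tools — with an all-pairs clique rule behind
`grouping = "clique"` for users who read "reciprocal correlation" strictly.
Components guarantee idempotence: representatives of different components
can never exceed the threshold with each other. CCREs may span genes;
gene-level roll-ups attribute a CCRE's calls to all member genes.

## The co-expression network

`correlation_adjacency()` builds the unsigned weighted adjacency
`a_ij = |cor(x_i, x_j)|^beta`. The robust correlation is the biweight
midcorrelation (tuning constant 9, Pearson fallback for zero-MAD rows),
with plain Pearson behind a flag. `select_soft_power()` implements the
scale-free topology criterion: the smallest power whose degree distribution
fits `log10 p(k) ~ log10 k` with R² at or above 0.8 and negative slope
(candidates 1..30 by default). At desk scale the data are far smaller than
a real transcriptome, so examples in this package use small powers (2–6);
the criterion itself is the decision rule either way.

`detect_clusters()` computes topological-overlap dissimilarity, clusters it
with average-linkage hierarchical clustering and a fixed-height cut
(default 0.98), labels clusters with colour-style names by decreasing size,
and sends groups below `min_size` to `"grey"`. The cut parameters are
configuration values; no claim is made that any particular count of
clusters matches a reference analysis. Subnetwork analyses always reuse the
main network's power and labels (`method = "provided"`).

**Topology statistics.** Within its cluster, each node gets connection
density `Kd_i = k_i / (N - 1)` (per-node degree over its maximum, so Kd is
in [0, 1] — required for `Hub <= Kd` and for the gamma/logit models
downstream), the Zhang–Horvath weighted clustering coefficient
`CC_i = sum a_ij a_jk a_ki / ((sum a_ij)^2 - sum a_ij^2)`, and the hub
score `Hub_i = Kd_i (1 - CC_i)`. High-density/low-CC nodes are *regulators*
(bridges between otherwise unconnected neighbours), high-density/high-CC
nodes *interactors*, low-density nodes *marginal*. Cluster summaries add
density, centralization `(N/(N-2)) (max Kd - density)`, degree
heterogeneity (coefficient of variation), median CC, and diameter — the
longest shortest path under the bounded distance `d = 1 - a` (the
alternative `1/a` is unbounded at `a = 0` and was rejected); edges with
`d = 0` are kept at a tiny positive weight so perfectly correlated pairs
remain adjacent.

## Differential expression

`fit_node_de()` fits `value ~ Stage + Stage:Sex` per node on the whole-body
samples: stage absorbs developmental change, and sex enters only through
one male-minus-female contrast per stage. Variances are moderated
empirical-Bayes style (the standard moderated-t machinery) unless
`moderation = FALSE`; splicing nodes are tested untransformed on their
ratio scale (a logit option was considered and left out of the default
path: ratios here rarely approach the boundaries after guarding, and
untransformed ratios keep coefficients interpretable as fraction changes).
Cluster-level tests apply the same model to module eigengenes — the first
principal component of the cluster's standardised node values, sign-
oriented to correlate positively with the cluster mean profile.

**Local FDR.** `compute_lfdr()` converts p-values to local false discovery
rates with a two-component model: `lfdr(p) = pi0 / f(p)`, where `f` is a
Grenander-type monotone density estimate and `pi0` is the upper-tail
fraction above 0.75 (rescaled). The monotone fit is evaluated on an
equal-count histogram lightly shrunk towards uniformity rather than on raw
order statistics: the raw Grenander estimator overshoots near zero (its
maximum slope exceeds 2 with probability one half under a true null), while
the binned variant is stable there. The price is that the alternative must
contribute appreciable probability mass — roughly 25 tests' worth — before
the density ratio registers it. That matches the node- and cluster-level
sweeps, where hundreds of contrasts are tested and real sex bias is
widespread, but it is the reason the power simulations in the test suite
plant effects in many units rather than one. Two places deliberately use
the raw order-statistic Grenander estimator instead, because they must
resolve individual extreme units against small test sets: linkage-group
enrichment (about two dozen p-values) and the permutation-calibrated
differential-correlation stages described below.

**Gene-level roll-ups.** A gene is sex-biased at a stage if any of its
transcription or splicing nodes is; genes ever male- and ever female-biased
are *switches*, tested for depletion against independence of the two
memberships with a one-tailed Fisher test, and excluded from linkage-group
enrichment. Gonad analysis contrasts testes with male pupae and ovaries
with adult females (`~ 0 + sex + sex:gonad`); a node is testis-flagged when
both its testis-versus-whole contrast and the testis-versus-ovary
interaction are significant in the testis direction (and symmetrically for
ovaries) — requiring the second contrast keeps genes elevated in both
gonads from being classed as tissue-specific. Cluster enrichment in gonad
flags uses one-tailed Fisher tests over clusters with at least five flagged
isoforms and Benjamini–Hochberg correction.

## Targeted differential correlation

The bespoke test asks whether a cluster's internal co-expression strength
differs between the sexes at a given stage, using only the 30 whole-body
samples.

**Subsampling.** For each stage, all C(6,3) = 20 ways of removing three of
its six samples are enumerated; the other stages keep all samples, so all
100 subnetworks have 27 samples (the only reading of the leave-three-out
design that keeps subnetwork size constant without a combinatorial
explosion). The sex composition of the three retained focal samples is the
signed balance `b = (#M - #F)/3`, which takes values −1, −1/3, +1/3, +1
with multiplicities 1, 9, 9, 1 and is exactly zero for every non-perturbed
stage. For every subnetwork, the adjacency is rebuilt on the retained
samples with the main network's power and labels, and every cluster's
within-cluster density plus the whole-subnetwork density are recorded
(compiled code; a pure-R engine is retained and cross-checked). Densities
are guarded into `(1e-6, 1 - 1e-6)` because the logit link is undefined at
the boundaries.

**Per-cluster GLM.** `Density ~ Stage + Stage:Balance + NetworkDensity`
with a gamma error distribution and logit link, fitted by IRLS. The
gamma/logit pairing is kept as the protocol's choice even though beta
regression is the textbook model for (0,1) responses. The stage-by-balance
Wald p-values are the test statistics. Because the 100 subnetworks share
samples, the rows are strongly dependent and the nominal p-values are far
from uniform — which is exactly why the test is calibrated by permutation
rather than read at face value.

**Permutation calibration.** Sex labels are shuffled within each stage
(preserving the stage structure of the design); a permutation changes no
density, only the balances, so each of the `n_perm` permutations re-derives
balances and refits the GLMs against the unchanged density table. Stage 1
maps each observed p through the ECDF of its own cluster's permutation
p-values pooled across stages, with two refinements the package treats as
part of its design: permutations whose focal-stage labelling equals the
observed one or its mirror image are dropped (they regenerate the observed
statistic, not a null draw — and with only 20 distinct relabelings per
stage they recur constantly), and the ECDF uses the usual finite-sample
floor `(# <= p + 0.5)/(n + 1)` rather than extrapolating below its
resolution. Pooling within cluster keeps each cluster calibrated against
its own dependence-driven statistic inflation; pooling across clusters was
tried and rejected because clusters with wild null tails masked everyone
else's evidence. The transformed values are converted to lFDR with the
order-statistic Grenander estimator; stage 2 recalibrates the stage-1
scores against each other the same way, and calls are made at stage-2 lFDR
below 10%.

**What this test can and cannot resolve.** Under the complete null the
procedure is cleanly calibrated (zero calls in 50-seed runs at desk scale).
Its power, however, is collective: with three replicates per sex there are
only 20 distinct within-stage relabelings, two of them degenerate, so a
single test's permutation evidence is bounded near rank 1/19 no matter how
many permutations are drawn, and the realised three-sample correlations
are themselves noisy. A single differentially-correlated cluster among
dozens of null clusters therefore sits at the detection boundary and is
usually not called; many differential clusters lower each other's lFDR by
sharing the floor of the calibrated distribution, which is the regime of a
full-scale transcriptome where a sizeable minority of clusters is truly
differential (and where the full protocol's 1000 permutations are worth
their cost). The validation suite and `scripts/acceptance.R` report the
single-cluster detection rate honestly rather than overstating it.

## Cluster architecture, model averaging and gene age

`pca_cluster_topology()` runs centred-and-scaled PCA on the eight cluster
statistics (size, density, centralization, heterogeneity, median CC,
diameter, and splicing/duplicated-gene proportions normalised by their
network-wide shares), with the deterministic sign convention that each
component's largest-magnitude loading is positive.
`model_average_binomial()` fits binomial GLMs for every predictor subset,
ranks them by AICc (`AIC + 2k(k+1)/(n-k-1)`, with `n` the number of
clusters and `k` the number of estimated coefficients), and reports each
predictor's relative importance (summed Akaike weights of the models
containing it; forced terms have RI exactly 1) alongside weight-averaged
coefficients (zero-filled over models omitting the term). RI above 0.70 is
the conventional reporting threshold. Complete separation triggers a
warning; a penalised-likelihood fallback was considered and deliberately
left off by default.

`fit_strata_models()` relates each node's connection density and hub score
to its gene's phylogenetic stratum (Metazoa .. Nasonia, oldest first;
Metazoa is the reference level) via
`y ~ ClusterSize + Stratum + DE + DC + Stratum:DE + Stratum:DC` with
gamma/logit errors, expanded into all marginality-respecting subsets with
ClusterSize forced, and AICc-averaged. DE and DC are cluster-level flags
propagated to member nodes; a cluster counts as DC regardless of DE status
and vice versa. Strata with fewer than five nodes merge into the closest
older stratum. `stratum_fold_enrichment()` reports, per bias class, each
stratum's proportion over the genome-wide proportion (1.5 = 50% more genes
of that age than expected; the pooled all-classes set is exactly 1 by
construction).

## The synthetic-data generator

`generate_expression()` and the node-level shortcut `generate_node_data()`
emulate the study design so every stage of the pipeline can be validated
without external data. Gene signals are cluster-correlated Gaussians on the
log2 scale (array-like; not count-based):

* a per-cluster stage profile (SD 1 log2 unit) gives clusters coherent
  developmental trajectories;
* a replicate-level residual (`bio_sd`, default 0.3) carries the
  within-cell correlation structure via a shared per-sample factor — the
  default reflects that replicates are pools of tens to hundreds of
  individuals, so between-pool biological variation sits well below the
  per-individual scale;
* measurement noise (`noise_sd`, default 0.2) is added per exon on the
  log2 scale.

Planted effects: differential expression adds a log2 shift to one
stage-by-sex cell of a cluster; differential correlation draws the focal
cell's samples with sex-specific within-cluster correlation; gonad
enrichment shifts listed genes in testis or ovary samples; linkage
enrichment plants sex bias in a fraction of a linkage group; and
stratum-topology patterns place young-stratum genes either as bridges
between two tight cliques of old genes (`young_hub`: lower density, higher
hub score; the bridge loadings alternate in sign so bridges stay mutually
uncorrelated, and these clusters carry no stage profile because with five
stage levels even independent profiles correlate enough to couple the
cliques) or as high-loading members of a single factor
(`young_interactor`: higher density). Facultative exons multiply the
gene's linear signal by a latent logistic splicing fraction; the planted
fractions are recoverable from the computed splicing ratios with pooled
correlation above 0.9 at `noise_sd` up to 0.3. A truth table records every
planted effect, and an optional flag mixes a fraction of male signal into
pre-pupal female samples to emulate brood contamination (off by default).

What the generator does **not** emulate: probe-level tiling-array
intensities and their noise-probe normalisation (the pipeline starts at
exon matrices), count-based noise, batch structure, or annotation errors.
Passing tests therefore validate the statistical machinery under the
declared model, not robustness to those artefacts.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the full suite completes
in minutes: differential-correlation calibration at 30 clusters of 60 nodes
with 200 permutations over 50 seeds; topology oracles on 1000 random
graphs of up to five nodes; effect-size recovery over 200 simulations;
gene-age pattern recovery at 12 clusters of 40 nodes over 50 seeds (at low
measurement noise, 0.02, so the planted architecture is faithfully realised
in the measured correlations). Fixed numerical details: type-1 quantile for
the floor; densities and topology responses guarded into `(1e-6, 1-1e-6)`;
IRLS convergence at relative step 1e-9 with 50 iterations and Wald t
p-values on the residual-degrees scale; CCRE representative ties broken by
higher mean value; eigengene sign by correlation with the cluster mean
profile; PCA signs by the dominant loading.

## Known limitations

Single-cluster differential-correlation detection at the three-replicate
design scale is granularity-limited (see above). The binned lFDR estimator
trades single-point sensitivity for null stability, so sparse weak signals
among few tests are conservatively missed. Gamma/logit is an approximation
for bounded densities; a beta-regression flag would be the natural
sensitivity analysis. CCREs collapse by single-linkage components, which
can chain through intermediate nodes in dense regions; the clique rule is
available where that matters.
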