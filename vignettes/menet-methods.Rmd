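---
title: "Mixed-effect neural genomic prediction with menet: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-effect neural genomic prediction with menet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menet)
```

## The model

Quantitative traits in breeding populations mix two kinds of genetic
signal. Classical mixed models separate them: *fixed* marker effects —
individual variants pushing the phenotype up or down — and a *random*
effect whose covariance is the genetic relatedness among individuals,
capturing the diffuse contribution of thousands of small-effect loci and
shared family background. Linear mixed models handle both terms well but
only additively; epistatic interactions
$\sum_{(i,j)\in C}\theta_{ij}X_iX_j$ are out of reach in practice because
the pair set $C$ cannot be enumerated.

`menet` implements MeNet, a dual-branch neural network that keeps the
mixed-model decomposition but lets both terms be nonlinear:

* **RepGeno** (random-effect branch): a fully connected encoder mapping a
  genotype vector to a unit-norm embedding, trained with a *trait-aware
  triplet loss*. For an anchor with positive (same family) and negative
  (different family) partners,
  $$L = \log\!\big(1 + e^{\,d^+ - d^- + m_\gamma}\big),
  \qquad m_\gamma = \Delta^- - \Delta^+ + \varepsilon\cdot\mathrm{margin},$$
  where $d^\pm$ are Euclidean distances between normalized embeddings and
  $\Delta^\pm$ the absolute phenotype differences of the pairs. The
  adaptive margin pushes embedding geometry to mirror phenotypic
  similarity, so scaled pairwise distances (`relatednessMatrix()`) act as
  a trait-specific kinship.
* **VE** (fixed-effect branch): a one-dimensional residual convolutional
  network over the marker sequence — convolution (kernel 3, stride 1,
  same padding), two ResNet-style residual blocks
  (conv–batch-norm–ReLU–conv–batch-norm plus the skip), adaptive average
  pooling to a fixed length, then fully connected layers. Adaptive
  pooling makes the embedding width independent of the marker count.
  Batch-normalization statistics used at prediction time are frozen from
  one pass over the training samples with the final weights, so
  predictions do not depend on the composition of the prediction batch.
* **Cross-information feature fusion**: with $z = [z_{VE}; z_{RepGeno}]$,
  each branch is corrected residually,
  $\hat z_{VE} = z_{VE} + F_{VE}(z)$ and
  $\hat z_{RepGeno} = z_{RepGeno} + F_{RepGeno}(z)$, by independent
  three-layer bottleneck networks; the corrected embeddings are
  concatenated into a three-layer prediction head.

Training is two-stage: stage 1 fits the RepGeno encoder with the triplet
loss; stage 2 freezes it and fits VE, fusion and head by AdamW on the
mean-absolute-error objective in minibatches of 128, with a
plateau-driven learning-rate schedule and checkpoint selection by
validation $R^2$. For genomes with more markers than `windowThreshold`
(default 100 000), `chromosomePartition()` assigns one VE instance per
chromosome (splitting oversized chromosomes into fixed windows); every
segment embedding is corrected against the concatenation of all
embeddings, the natural extension of the two-branch fusion above.

### Transfer across environments

`transferFinetune()` implements the cross-environment protocol: the
RepGeno encoder, the VE trunk(s) and $F_{RepGeno}$ are frozen; only
$F_{VE}$ and the prediction head are retrained on a small fraction of
target-environment samples (default 10%, split 5% training / 5%
validation). The intuition follows the mixed-model reading: genetic
relatedness is an environment-stable property of the population, while
the expression of variant effects shifts with environment and is cheap to
re-calibrate through the low-dimensional correction pathway.

### Branch attribution

`attributeContributions()` quantifies how much each branch drives the
prediction using integrated gradients on the fused embedding with a zero
baseline,
$$IG_i(z) = z_i \int_0^1 \frac{\partial F(\alpha z)}{\partial z_i}
\,d\alpha.$$
Because the network is piecewise linear, the path gradient is piecewise
*constant* in $\alpha$: a fixed-grid rule (midpoint or trapezoid)
converges only at rate $O(1/\text{steps})$, too slowly for tight
completeness. The default integrator therefore evaluates the gradient on
a base grid (256 intervals by default) and adaptively bisects any
interval whose midpoint gradient departs from its endpoint average —
which for this function class happens exactly where an activation
boundary is crossed — until each piece is constant; constant pieces and
locally linear pieces are integrated exactly. The plain midpoint rule
remains available (`refine = FALSE`). Branch scores sum
the mean absolute attribution over each branch's named index set,
$S_{VE} = \sum_{i\in VE}\frac1N\sum_j |a_{j,i}|$ (likewise
$S_{RepGeno}$), and are normalized to weights $w_{VE} + w_{RepGeno} = 1$.
On oligogenic traits the weight settles on VE; on polygenic,
family-structured traits it shifts to RepGeno — the attribution recovers
the trait's genetic architecture.

The completeness identity $\sum_i IG_i \approx F(z) - F(0)$ is the
practical accuracy check; with the adaptive integrator it holds to
numerical precision, and doubling `steps` until the attributions move by
less than 1% remains a useful end-to-end sanity test.

## What the simulator emulates — and what it does not

`simulateGenotypes()` produces multi-family inbred panels in the spirit
of RIL/MAGIC breeding populations: fully homozygous genotypes (signed
codes $\pm 1$), families with diverged allele frequencies, and LD blocks
generated by drawing two founder haplotypes per family and block
(biparental style) that members copy with a per-marker mutation
probability. `mutationRate` tunes within-block $r^2$ monotonically;
`mutationRate = 1` gives independent markers. `simulateTrait()` implements
the nonlinear mixed model literally: intercept, additive effects,
pairwise products over an explicit pair set, a family-level random effect
(constant within family), per-environment effect scaling and Gaussian
noise. Noise variance is solved from the *realized* genetic variance so
the target heritability holds under epistasis too, rather than assuming a
theoretical variance. Per-marker environment scalings multiply additive
effects directly; an epistatic effect is scaled by the mean of its two
marker scalings (the product form makes any elementwise convention
arbitrary; this one keeps a scalar profile equivalent to scaling the
whole genetic score). `correlatedEnvProfiles()` constructs two
environments whose genetic values correlate at a chosen $\rho$.

The simulator does **not** model recombination maps, dominance (the trait
model has no heterozygote-specific term, and inbred panels have no
heterozygotes), genotyping error, or coalescent-realistic allele
frequency spectra. Tests passing on these panels demonstrate the
machinery — preprocessing exactness, loss algebra, attribution axioms,
directional behaviours such as transfer gains — not field-scale accuracy
on real crops.

## Fixture scales and study conditions

The package's own checks run at desk scale, chosen once: nonlinearity
capture uses $n = 2000$, $p = 500$ with 20 epistatic pairs at
$h^2 = 0.6$ in a panmictic MAF-0.5 panel, so that the pairwise products
are exactly orthogonal to the additive span and a ridge oracle's test
$R^2$ is the noise floor; pairs sit on adjacent markers inside LD blocks,
the haplotype-level interactions a kernel-3 convolution can legitimately
see. Contribution recovery contrasts an oligogenic panel (5 large loci,
$h^2 = 0.8$, weak structure) with a polygenic one (500 tiny effects plus
a strong family effect). Transfer uses $n = 800$, $p = 300$, two
environments at genetic correlation 0.7 and $h^2 = 0.7$. Embedding
geometry uses $n = 600$, $p = 500$, three families. Architecture defaults
at this scale are 4 convolution channels, embedding dimension 16–64,
pooling length 16–64 and 10–60 epochs; the published grids (channels up
to 64, embeddings 512–8192) remain available through `gridSearch()` for
full-scale data.

## Numerical and design choices

* **Genotype coding**: hom-alt $\to 1$, hom-ref $\to -1$, het $\to 0$,
  missing $\to 0$. The orientation of the homozygotes is a convention
  (flipping signs of a column is absorbed by the first layer); note that
  heterozygous and imputed-missing calls are indistinguishable after
  coding — a property of the coding, documented rather than "fixed".
  Minor allele frequency is computed from the codes as
  $(\bar x + 1)/2$ folded at 0.5.
* **LD pruning**: greedy within sliding windows (2000 bp window, 1000 bp
  step by default), $r^2$ as squared Pearson correlation of encoded
  columns, keeping the earlier-position marker of a violating pair — a
  deterministic tie-break; chromosomes pruned independently. A
  marker-count window mode (`windowType = "count"`) mirrors PLINK's
  `--indep-pairwise` convention.
* **Embedding alignment**: both branch embeddings are L2-normalized
  before fusion. RepGeno's normalization is part of its loss geometry;
  normalizing VE to the same unit scale aligns the two information
  vectors so that fusion corrections and integrated-gradients
  attributions compare like with like rather than reflecting arbitrary
  scale differences.
* **Correction-network init**: the output layers of $F_{VE}$ and
  $F_{RepGeno}$ start at zero, so fusion begins exactly at the residual
  identity $\hat z = z$ and corrections grow only as the data demand.
* **Relatedness scaling**: unit-norm embeddings have a maximum pairwise
  distance of 2, so distances are divided by 2 (analytic $[0,1]$
  scaling); min–max scaling is available as an option.
* **Phenotype scale**: phenotypes are z-scored on the training samples
  before triplet deltas (making $\varepsilon \cdot \mathrm{margin}$
  scale-free) and before stage-2 regression (predictions are returned in
  trait units).
* **Schedules**: plateau patience 10, factor 0.5, minimum learning rate
  $10^{-6}$, early stop after 30 epochs without validation improvement;
  one triplet per anchor per epoch, resampled every epoch.
* **$R^2$ convention**: squared Pearson correlation between predicted
  and observed by default (affine-invariant, the convention under which
  comparisons to heritability are meaningful); the
  $1 - SS_{res}/SS_{tot}$ form is available via `r2Method = "ss"`.
  Degenerate cases (constant vectors) report a correlation of 0 with a
  warning. NMSE is MSE$/\mathrm{Var}(y)$, RRMSE is RMSE$/\bar y$, MAPE
  excludes zero-valued observations.
* **Ridge oracle**: closed-form SVD solution with unpenalized intercept;
  $\lambda$ by generalized cross-validation when unspecified.
  $\lambda = 0$ with $p > n$ is refused as singular.
* **Determinism**: every stochastic entry point takes a seed; one
  top-level seed expands deterministically into per-component seeds, so
  a pipeline run is bit-reproducible.

## Open choices made here

The architecture around the published skeleton needed several decisions
the description leaves open: the RepGeno encoder is a two-layer MLP (the
encoder family is unspecified); the embedding fed to fusion is the
encoder output itself rather than a vector of distances to reference
samples (`relatednessMatrix()` exposes the distance view separately);
both branches share one embedding dimension; convolution kernel 3 with
two-convolution residual blocks is the smallest faithful reading of the
VE description; and stage 2 keeps the RepGeno encoder frozen — the
transfer protocol treats it as a separable unit, which only makes sense
if stage 2 does not entangle it (`trainMeNet()` is written so a joint
fine-tuning variant can be added, but the frozen default is the
protocol's own logic). Where the fused order $[z_{VE}; z_{RepGeno}]$
versus $[z_{RepGeno}; z_{VE}]$ is ambiguous in the description, branch
membership is tracked by named index sets, never by position.

## Known limitations

Hand-written backpropagation in base R is CPU-bound: desk-scale panels
(hundreds to a few thousand samples, hundreds of markers) train in
seconds to minutes, but full-scale panels (tens of thousands of samples,
$10^5$ markers) need the published GPU setting rather than this
implementation. The label-free triplet fallback degrades gracefully but
learns more slowly than labelled sampling. MAPE is undefined for traits
centred at zero. Attribution is at the embedding level by design;
SNP-level attribution and epistasis-pair identification are out of
scope.
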