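---
title: "Consensus mapping of maize stalk-lodging QTLs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus mapping of maize stalk-lodging QTLs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizeMQTL)
```

## The problem

Dozens of maize mapping experiments have reported QTLs for stalk-lodging
traits — plant and ear height, rind penetrometer resistance, internode
length, cell-wall composition, vascular-bundle anatomy — but each study uses
its own population, marker set and linkage map, so the reported loci cannot
be compared directly. Meta-QTL analysis places all reported QTLs on one
reference map and asks which of them co-locate tightly enough to represent
the same underlying locus. The consensus loci (MQTLs), once narrowed and
cross-validated against GWAS signals, become usable targets for
marker-assisted selection and candidate-gene search.

This package implements that workflow as five composable stages — curation,
projection, mixture-model clustering, GWAS validation, gene scoring — plus a
seeded synthetic-data generator with exported ground truth, so every stage
is testable against known answers.

## Curation and imputation

A usable QTL record needs a peak position, a 95% confidence interval and an
effect size. Published tables are incomplete in predictable ways, and the
curation stage fills the gaps with standard empirical rules, never
overwriting a reported value:

* missing peak — the midpoint of the flanking markers' positions on the
  record's own study map;
* missing $R^2$ (proportion of phenotypic variance explained) — from the
  peak LOD score and population size $N$:
  $R^2 = 1 - 10^{-2\,\mathrm{LOD}/N}$;
* missing confidence interval — the population-size width rule, centred on
  the peak: $\mathrm{CI} = 530/(N R^2)$ cM for F2- and backcross-derived
  populations, $\mathrm{CI} = 163/(N R^2)$ cM for recombinant-inbred-line
  populations.

Doubled-haploid populations are routed with the RIL formula (fully
homozygous lines with comparable effective recombination), F2:3 and
immortalized-F2 populations with the F2 formula; the routing is a
configuration argument because the width rules are published only for the
two canonical designs. The $R^2$ formula divides the exponent by $N$ and is
implemented exactly in that printed form; its inverse is used by the
generator so LOD and $R^2$ are always mutually consistent.

Records that cannot be completed are kept with `usable = FALSE` and a
reason string rather than dropped, so exclusion accounting is auditable at
every stage. Reported percentages are rounded half-up at the number of
decimals used in published summary tables (base R's `round()` rounds half
to even, which disagrees with those tables).

## Projection onto the reference map

Study maps are placed on a common high-density reference map by homothetic
projection: within each interval bounded by consecutive markers shared (by
exact name) between the study map and the reference map, positions map
linearly so that the shared markers coincide. Peaks and both CI bounds are
projected independently, each with its own flanking pair, which makes the
mapping piecewise-linear across intervals — the natural reading when a CI
spans several common-marker intervals.

Design choices that needed a decision:

* **No extrapolation.** A position outside the span of the common markers is
  excluded (`excluded_out_of_range`), mirroring the exclusion of QTLs whose
  projections fall off the reference map; end-interval ratios are too
  unstable to extrapolate with. A CI *bound* that individually leaves the
  span is clamped to the chromosome end instead, because the peak — the
  quantity the mixture model consumes — is still well-defined.
* **Inconsistent markers are dropped, not repaired.** A shared marker whose
  reference order contradicts its study order against *any* other shared
  marker is excluded from anchoring. Local marker-order disagreements
  between maps are a known reality; dropping both members of an inverted
  pair is conservative and logged.
* **Positional uncertainty.** The mixture model needs a standard deviation
  per projected QTL. The projected interval is read as a 95% CI under
  normality: $s_i = (\text{CI width})/3.92$, i.e. $1.96\sigma$ half-widths.
  A floor of 0.01 cM guards against zero-width intervals.

The projection obeys exact invariants — identity on equal maps, exactness
under affine map relations, order preservation — that the test suite checks
on hundreds of randomized map pairs.

## The consensus-clustering model

On one chromosome, the projected peaks $x_1,\dots,x_n$ with known standard
deviations $s_1,\dots,s_n$ are modelled as a $K$-component Gaussian mixture

$$ p(x_i) = \sum_{k=1}^{K} \pi_k\, \mathcal{N}(x_i;\ \mu_k,\ s_i^2), $$

in which only the consensus positions $\mu_k$ and mixing proportions
$\pi_k$ are free — the per-observation variances are fixed at the values the
CIs imply. EM alternates responsibilities
$r_{ik} \propto \pi_k \mathcal N(x_i; \mu_k, s_i^2)$ with precision-weighted
mean updates $\mu_k = \sum_i r_{ik} x_i / s_i^2 \big/ \sum_i r_{ik}/s_i^2$
and $\pi_k = n^{-1}\sum_i r_{ik}$, stopping when the log-likelihood moves
by less than $10^{-8}$ or after 500 iterations. Initialization is
deterministic (component means at the $k/(K{+}1)$ precision-weighted
quantiles of $x$) plus ten seeded jittered restarts, and the best run by
log-likelihood is kept — this avoids label-switching instability while
remaining reproducible.

$K$ is chosen by minimizing an information criterion over $K = 1..\min(n, 10)$
with $p = 2K-1$ free parameters (variances are known, so only means and
weights count): AIC ($-2\ell + 2p$, the default), AICc, AIC3, BIC, and AWE.
AWE is computed on the classification log-likelihood (hard MAP assignments),
following the Banfield–Raftery convention, since only the criterion's name
is standard. Ties break toward smaller $K$; fits with an empty component are
flagged degenerate and excluded from selection.

Each QTL is then hard-assigned to its maximum-responsibility component.
Hard membership matches the discrete "MQTL integrates $m$ initial QTLs"
accounting of consensus-mapping practice, and drives the consensus CI: for
component $k$ with members $M_k$,
$\mathrm{sd}_k = (\sum_{i \in M_k} s_i^{-2})^{-1/2}$ and the 95% CI is
$\mu_k \pm 1.96\,\mathrm{sd}_k$.

The EM is cross-checked three independent ways in the tests: the $K=1$
closed form (inverse-variance weighted mean) to $10^{-9}$; per-iteration
log-likelihood monotonicity on random instances; and, for $n \le 6$ and
$K \le 2$, an exhaustive grid search over means on a 0.01 cM lattice and
mixing proportion on a 0.01 lattice, which the EM must match within
$10^{-4}$ log-likelihood.

## Physical reconciliation, GWAS validation and filters

Consensus CIs are converted to physical coordinates by piecewise-linear
interpolation between the reference markers that carry bp positions. A
query cM is clamped into the anchored span first: consensus 95% CIs
legitimately overhang the mapped chromosome ends (they are $\mu \pm
1.96\,\mathrm{sd}$), and truncating at the boundary keeps the locus usable
instead of discarding it.

The downstream filters follow strict printed thresholds, verified at their
exact boundaries in the tests:

* **GWAS co-localization**: an MTA validates an MQTL when it lies within
  500 kb of the physical interval, bounds inclusive; trait identity is not
  required by default (positional overlap only), with a strict-trait mode
  available.
* **Breeder's MQTL**: $\ge 2$ member QTLs, physical span $< 1$ Mb
  (strict), 95% CI width $< 4$ cM (strict).
* **MTA-supported gene windows**: strictly more than 3 co-localized MTAs
  (configurable, since "more than three" vs "three or more" readings both
  appear in practice); the gene-search window is the whole interval when it
  spans under 1 Mb, otherwise 500 kb each side of the consensus peak. The
  peak's physical position is the interpolated consensus position — a
  self-contained approximation to external peak-estimation formulas.
* **Core MQTLs**: the non-redundant union of the breeder and MTA-supported
  sets.

## Candidate genes and evidence scoring

Candidates are the union of genes overlapping breeder's-MQTL intervals,
genes in MTA-supported windows, and ortholog-supported genes inside any
MQTL interval. Gene–window overlap requires at least 1 bp of the gene body
in the closed window — the simplest auditable rule. Four binary evidence
flags each score one point: breeder's-MQTL localization, GWAS-window
localization, a rice ortholog passing the protein-alignment filter
($E < 10^{-10}$ and identity $> 60\%$, both strict), and expression above
FPKM 2 (strict) in at least one tissue. "Relevant tissue" is deliberately
operationalized as *any* provided tissue, with a tissue-subset argument,
because no fixed definition exists; the ortholog point likewise uses the
alignment filter alone, with room for a curation override upstream.
Tiers: score $\ge 3$ high (four-point genes are folded into the high tier
but remain visible via the score), 2 medium, 1 low, 0 unsupported. Tier
percentages are reported over genes with at least one point, to 2 d.p.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *geometry* of a real compilation: a reference
map with an expanded cM scale (800 cM over 150 Mb per chromosome, about
0.19 Mb/cM — high-density reference maps are several-fold longer in cM than
individual study maps); study maps that subsample 40% of reference markers
over a contiguous span and compress each interval by an independent factor
in [0.18, 0.35]; twelve studies, three chromosomes, three true loci per
chromosome at least 100 cM apart on the reference scale; 8–20 QTL reports
per locus with population types and sizes drawn from a realistic mix;
$R^2$ log-normal and clipped to the published range (1.3%–43%); LOD set by
inverting the $R^2$ formula so imputation round-trips exactly; and
configurable fractions of records with the CI (30%), $R^2$ (20%) or peak
(10%) blanked.

Two deliberate choices shape what the recovery tests mean:

* **Reported precision is not true precision.** Each record's reported CI
  width follows the population-size formula, while its *true* positional
  scatter around the generating locus is drawn independently (0.5–3 cM on
  the reference scale, a small fraction of typical projected CI widths —
  the regime where co-locating QTLs genuinely share a locus). This
  misspecification is a realistic stressor for the precision-weighted
  consensus estimator: its error is driven by the few highest-precision
  records. A `well_specified` mode sets reported width equal to true
  scatter for clean recovery baselines.
* **True loci are GWAS-supported.** Each locus receives Poisson(8) MTAs
  scattered 200 kb around it, plus Poisson(5) background MTAs per
  chromosome. Strongly validated consensus loci in real compilations carry
  on the order of ten or more MTAs; the default represents loci of that
  kind, which is what makes "core-MQTL windows recover causal genes" a
  well-posed expectation.

The generator does **not** emulate: epistasis or multi-QTL linkage within a
chromosome arm, LD structure around MTAs (the ±500 kb window is a fixed
convention, not LD-aware), marker genotyping error, shared parents between
studies (records are independent given the locus), or realistic marker
names. Passing recovery tests therefore demonstrates that the pipeline's
machinery is correct under its stated model, not that the model captures
every failure mode of real compilations.

A separate, smaller simulator (`simulate_mixture_instance()`) draws directly
from the clustering observation model — three loci at least 20 cM apart,
8–20 observations each, $s_i \in [1,5]$ cM — for parameter-recovery tests
of the mixture stage in isolation, where reported and true precision
coincide by construction.

## Numerical conventions and problem sizes

* cM as decimals; bp 1-based; all internal intervals closed on both ends;
  BED export converts to 0-based half-open exactly.
* EM tolerance $10^{-8}$ absolute log-likelihood change, 500 iterations
  maximum, 10 restarts; observation-sd floor 0.01 cM.
* Ties: criterion ties toward smaller $K$; responsibility ties toward the
  lower-indexed component.
* Half-up rounding for all reported percentages.
* Seeds: one root seed; every stage and replicate derives its own stream
  from it, so whole-pipeline runs are byte-reproducible.
* Default validation sizes, chosen to make the full suite convenient on a
  single CPU: 50 replicates for mixture recovery, 20 seeded datasets for
  end-to-end gene recovery, 100–200 randomized cases for projection and EM
  property tests.

## Known limitations

The two-step procedure fixes per-QTL variances from reported CIs, so
systematically optimistic reporting biases consensus positions toward the
over-precise studies; the generator's misspecification stressor quantifies
this but the pipeline does not correct it. Chromosomes are analysed
independently. Model selection considers a single criterion at a time
(all five are always reported). Physical reconciliation assumes cM→bp
monotonicity between anchored markers and interpolates through whatever
local inversions the reference map carries.
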