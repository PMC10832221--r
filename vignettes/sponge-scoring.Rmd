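---
title: "Scoring circRNA–miRNA sponge mechanisms: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring circRNA-miRNA sponge mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongescan)
```

## The model

A circRNA acts as a miRNA sponge when it carries enough high-affinity
miRNA recognition elements (MREs) to sequester a well-expressed miRNA,
de-repressing that miRNA's mRNA targets. `spongescan` operationalises this
as a multi-criteria ranking problem over (miRNA, circRNA) pairs, under
three biological prerequisites:

1. **miRNA sufficiency.** A sponge can only matter for a miRNA that is
   actually present. A miRNA is retained when its summed expression is
   nonzero and its expression exceeds a cutoff in *strictly more than*
   90 % of samples. The cutoff is the first quartile (Q1) of the pooled
   value distribution of the whole miRNA matrix, computed with the
   linear-interpolation (type-7) quantile. Both comparisons are strict.
   The miRNA is *not* required to be differentially expressed: sponging
   changes its bioavailability, not its level.
2. **Connectivity.** The miRNA must target at least one circRNA and at
   least one mRNA with sufficient predicted affinity.
3. **Co-direction.** The circRNA and at least one of the miRNA's mRNA
   targets must be differentially expressed in the *same* direction
   between the two conditions — the expected signature of de-repression.
   Direction is the sign of the log2 fold change (condition 2 minus
   condition 1, a plain difference because inputs are log2); features with
   exactly zero fold change are ineligible. No minimum magnitude is
   imposed: inputs are expected to be pre-restricted to differentially
   expressed circRNAs and mRNAs by the user, so the package performs no
   statistical DE testing of its own.

## Interaction-reliability criteria

Site-level predictions (one row per MRE, TargetScan-style context scores)
are collapsed to one record per (miRNA, target): the MRE count and the
*best* raw score. We adopt the TargetScan sign convention — lower (more
negative) scores mean stronger predicted repression — so "maximum
affinity" is the minimum raw score. From these:

* **S_Affinity** — min–max rescaling of the best raw score to [0, 1]
  within each target-type table (context+ and context++ scores share no
  scale, so circRNA and mRNA tables are rescaled independently; a
  constant column maps to 0.5 by convention).
* **S_NbMRE** — for circRNA targets, MREs per nucleotide of spliced
  sequence (long circRNAs accumulate sites by length alone); for mRNA
  targets, the raw count.
* **S_EnrichMRE** — an upper-tail binomial test asking whether circRNA
  *c* is enriched in MREs for miRNA *m*: with `k` sites of *m* on *c*,
  `N` total sites on *c* and background probability `p0` equal to *m*'s
  share of all circRNA sites, the p-value is `P(X >= k)` for
  `X ~ Binomial(N, p0)`. BH adjustment runs over all pairs tested in one
  run (one screen, one family); pairs with adjusted p < 0.05 survive. A
  configuration switch removes the focal miRNA's own sites from the
  background; the default keeps them, which is slightly conservative.

When a validated-interaction table is supplied, an **affinity cutoff** is
calibrated as the 95th percentile (linear interpolation) of the best
scores restricted to pairs with at least two CLIP-seq *and* two
degradome-seq experiments; predicted pairs are kept iff their best score
is `<=` the cutoff, i.e. binds at least as strongly. Two open points are
resolved as package defaults and exposed in the configuration: the cutoff
keeps the stronger-than-cutoff side (the alternative would discard
exactly the experimentally supported score range), and no cutoff is
applied to miRNA–mRNA pairs (calibration is circRNA-based; context++
scores already integrate false-positive-limiting features).

## Expression criteria

* **S_FC** — difference of per-condition means on the log2 scale. The
  *sign* feeds the co-direction filter and the condition assignment; the
  *magnitude* enters TOPSIS, because "more differentially expressed" is
  only coherent on magnitude. A flag restores signed values.
* **S_MirExpr** — per-miRNA median over all samples, conditions pooled.
  When a miRNA signature replaces the matrix, signature values pass
  through verbatim (signatures are assumed pre-filtered by the same Q1
  rule, so the sufficiency filter is skipped) and cross-dataset
  comparability is the user's responsibility — a note is logged.
* **S_TargetExpr** — the larger of the two per-condition means: a sponge
  needs the target present in at least one condition.

## TOPSIS integration

Both integrated scores use canonical Hwang–Yoon TOPSIS: vector
normalisation of each criterion column (`x / sqrt(sum(x^2))`; an all-zero
column stays zero), multiplication by weights (uniform by default — no
evidence justifies anything else; a weight vector is configurable),
Euclidean distances to the ideal/anti-ideal points, closeness
`C = d^- / (d^+ + d^-)`. Degenerate cases (a single alternative, or all
alternatives identical) return 0.5 by convention. Vector normalisation
makes `C` invariant to positive rescaling of any criterion, which matters
because the criteria live on wildly different scales (sites per
nucleotide vs. log2 expression).

`SG` is one joint TOPSIS run over *all* eligible miRNA–mRNA pairs (not
per-miRNA pools), five benefit criteria. `SS` is one joint run over all
eligible miRNA–circRNA pairs, five benefit criteria plus the two adjusted
enrichment p-values as *cost* criteria, entered raw ("minimise the
adjusted p-value" taken literally; a `-log10` transform is available
behind a flag). Per-condition ranks are derived afterwards from the
global ranking, so a mechanism has both a global and a within-condition
rank.

## S_EnrichSG: preranked enrichment of a miRNA's interactions

All miRNA–mRNA pairs are ranked by SG descending (ties broken by the
stable lexicographic (miRNA, mRNA) order). For each miRNA, its pairs form
a set whose concentration at the top of the list is measured by the
weighted Kolmogorov–Smirnov running-sum statistic with weight exponent 1
on the SG values — the classical preranked-GSEA form. The p-value is
one-sided for positive enrichment:

* **exact** when the number of equally likely same-size sets
  `choose(n, k)` is at most 1e5: exhaustive enumeration, p = fraction of
  sets with ES at least the observed value;
* **sampled** otherwise: `nperm` seeded uniform draws with the
  `(1 + hits) / (nperm + 1)` correction.

The exact/enumeration route was chosen over an adaptive multilevel
estimator deliberately: it is verifiable against brute force, and the
p-values here feed a rank, not a significance claim. `nperm` defaults to
10,000 and the seed is mandatory, so reruns are bit-identical. BH
adjustment across all miRNAs in the run gives `S_EnrichSG`, broadcast to
every circRNA pair of that miRNA.

## Numerical conventions and degenerate inputs

* Quantiles everywhere are type-7 (linear interpolation), matching the
  stated Q1 and 95th-percentile rules.
* BH is implemented in-package as the textbook step-up (`p * n / rank`,
  monotonicity from the largest down, capped at 1) so that every BH
  family in the pipeline shares one exact implementation.
* Ties in ranking are broken by lexicographic identifiers, making the
  score matrix a deterministic function of inputs and seed.
* Empty stages raise classed errors naming the stage that emptied the
  candidate set rather than returning empty tables silently.
* The score-matrix writer prints floats with 17 significant digits, so
  write→read round-trips are lossless and snapshot comparisons can be
  byte-exact.

## The synthetic generator: what it emulates and what it does not

`generate_fixture()` produces the full input bundle: log2-scale
expression = baseline + condition effect + Gaussian noise (log-normal in
linear space, consistent with "normalised and log-transformed" inputs),
sparse weak background sites, spliced lengths uniform in [300, 2000] nt,
and a validated table mixing solid and weak evidence. Defaults state the
reference world: 200 circRNAs, 500 mRNAs, 50 miRNAs, 6 + 6 samples, one
planted mechanism at full strength, noise SD 0.5 log2 units, background
site rate 0.02 per (miRNA, target) pair, decoy effect sizes U(0.8, 2) in
random directions — values a desk-scale transcriptomics simulation would
call realistic, fixed once.

A planted mechanism at strength 1 is *constructed to dominate*: circRNA
up 4 log2 units in condition 2, miRNA baseline 9.5 (above any decoy),
MREs at roughly one per 80 nt with the most negative scores in the table,
and five mRNA targets co-up-regulated. Scaling the planted MRE count with
the drawn circRNA length keeps the sites-per-nucleotide criterion
dominant for any length in [300, 2000]. At strength 0 every planted
property collapses onto the background distributions.

The generator does **not** emulate read-count noise, normalisation
artefacts, correlated co-expression networks, shared MRE sequence
families, or miRNA-mediated repression itself (decoy expression is
independent of the site tables). A green planted-recovery test therefore
establishes that the pipeline's filters and ranking behave as specified
on a favourable, well-separated instance — not that the method has power
on real tumour data, which depends on upstream DE restriction and
prediction quality outside this package's control.

## Known limitations

* No differential-expression testing, normalisation or batch handling:
  inputs are assumed pre-processed and pre-restricted.
* MRE prediction is upstream; the package consumes score tables and
  cannot correct their biases. The sign convention (lower = stronger) is
  assumed, not checked against the predictor.
* TOPSIS rank reversal (removing an alternative can reorder others) is
  inherent to the method and documented as expected behaviour; only the
  single-criterion case is guaranteed order-stable.
* The enrichment web service is replaced by a local hypergeometric
  over-representation test on user-supplied GMT files; no curated KEGG/GO
  libraries ship with the package, and result ordering is by p-value, not
  by any combined score.
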