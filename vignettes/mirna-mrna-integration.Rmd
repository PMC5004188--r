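---
title: "Identifying miRNA-regulated pathways from paired expression cohorts"
author: "mirpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying miRNA-regulated pathways from paired expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpath)
```

## The problem

MicroRNAs repress their target mRNAs post-transcriptionally, so a miRNA that
matters in a disease should leave two fingerprints in a paired expression
cohort: it is differentially expressed between cases and controls, and its
expression tracks its targets' expression *inversely* across subjects.
Neither fingerprint alone is convincing — differential expression lists are
long, anti-correlations arise by chance, and sequence-based target
predictions are notoriously over-inclusive. The integration strategy
implemented here requires all three lines of evidence at once, then asks
which annotated pathways the surviving targets concentrate in and which
miRNAs dominate the resulting regulatory network.

The pipeline was designed for the small paired cohorts typical of clinical
profiling — on the order of a dozen cases and half a dozen controls assayed
on miRNA and mRNA microarrays (RMA-normalised, hence log2 scale throughout).
The motivating application is CD34+ hematopoietic cells in myelodysplastic
syndromes, but nothing in the code is tissue-specific.

## The statistical core

### Moderated t-tests under the random variance model

With 3–12 samples per group, per-feature variance estimates are unstable and
ordinary t-tests lose power erratically. The random variance model (RVM)
assumes each feature's true variance is drawn from an inverse-gamma prior,
$\sigma^{-2} \sim \Gamma(a, b)$, under which the observed residual variance
$s^2$ with $d$ degrees of freedom satisfies $s^2 a b \sim F(d, 2a)$. The
hyperparameters are fitted once per matrix by maximising the marginal
likelihood of all residual variances (`fit_rvm_prior()`), and each feature's
test then uses the posterior-mean variance

$$\tilde s^2 = \frac{d\,s^2 + 2/b}{d + 2a},$$

with $t = (\bar x_{case} - \bar x_{control}) / \sqrt{\tilde s^2 (1/n_1 +
1/n_2)}$ referred to $t_{d+2a}$. The $2a$ extra degrees of freedom are the
entire point: information is shared across thousands of features, exactly as
in limma's empirical-Bayes moderation, but with the F-likelihood fit used by
the RVM literature.

Numerical choices: the likelihood is maximised over $(\log a, \log b)$ with
a fixed start ($a = 1$, $b = 1/\overline{s^2}$), Nelder–Mead followed by a
BFGS polish at relative tolerance 1e-8, so the fit is deterministic.
Zero-variance features are excluded from the fit (with a warning) but still
receive moderated statistics — with $s^2 = 0$ the formula reduces to the
prior term alone. One caveat documented deliberately: sending $a \to 0$
alone does *not* recover the ordinary pooled t-test, because the prior
contribution $2/b$ persists in the numerator; the reduction requires a
diffuse scale as well ($b \to \infty$), and the test suite checks the limit
that way. On homoscedastic data the fitted $a$ can grow very large — that is
the correct ML behaviour (the prior collapses onto the common variance) and
the resulting test is essentially a z-test against the global variance.

### Differential-expression gates

Features are called up/down by three joint gates, each individually
configurable: signed linear fold change of at least 1.5 in magnitude,
Benjamini–Hochberg FDR below 0.1, and p below 0.05. Fold changes use the
field's signed convention: the case/control ratio $R = 2^{\overline{\Delta
\log_2}}$ is reported as $+R$ when $R \ge 1$ and $-1/R$ otherwise, so
"−7.70" means 7.7-fold down. Both statistical gates are applied jointly
because both conventions circulate for this design; either can be disabled
by setting its threshold to 1.

### Anti-correlation screening and prediction intersection

For every (DE miRNA, DE mRNA) combination, the Pearson correlation is
computed across *all* samples, cases and controls pooled — the group
contrast itself carries most of the signal when a repressed target moves
opposite to its miRNA. The p-value is the exact t transform at $n-2$ df;
pairs need $r < 0$ and $p < 0.05$ (an optional $|r|$ floor and an optional
strict direction-concordance flag exist but default off, since the negative
correlation gate subsumes concordance). Surviving candidates are then
intersected with a two-column miRNA→gene prediction table — a TargetScan
snapshot in practice, any curated list in principle. Only the intersection
is called a *target relationship*. Pairs with fewer than 4 samples or a
zero-variance profile are skipped with a warning rather than given a
meaningless p.

### Enrichment

Target genes of up- and of down-regulated miRNAs are tested separately
against pathway (KEGG-style) and GO collections read from GMT. Each set's
2×2 table is tested two ways: the two-tailed Fisher exact test under the
minimum-likelihood convention (sum of all hypergeometric point
probabilities not exceeding the observed one, with a 1e-7 relative tie
guard, matching `stats::fisher.test`), and the 1-df Pearson chi-squared test
without continuity correction. BH FDR is computed over each collection from
the Fisher p, and both significance tiers (p < 0.05, FDR < 0.05) are
emitted as separate columns, since published analyses of this design report
both. The universe defaults to all genes on the (probe-collapsed) mRNA
matrix restricted to the annotated genes — the standard enrichment
background choice; it is configurable because no single convention is
universal. "Key targets" are the pair genes belonging to at least one
significant pathway set *and* one significant GO set.

### Network degree and regulated pathways

Screened pairs define a bipartite graph; the adjacency matrix carries genes
in rows and miRNAs in columns, with binary weights by default (an $|r|$
weighting is available, but degree is always the unweighted count of
incident edges — "number of targets" is a count). Regulators are miRNAs
with degree strictly over 3, hubs strictly over 10; the strict reading of
"over" is deliberate and matches the published degree table this package
ships as a fixture (`mds_pathway_table()`), where the regulator tier is
exactly {miR-19a, miR-148a, miR-195}. Finally, pairs are joined with
significantly enriched pathways: one record per (pair, pathway with the
gene as member), carrying the miRNA's direction and fold change —
Table-1-style rows such as (miR-195, Up, 6.04, DLL1, Notch signaling
pathway). A gene annotated to several enriched pathways legitimately yields
several records.

## The synthetic world

`simulate_cohort()` generates the stated study design: 12 cases vs 6
controls, ~2,500 miRNA and ~20,000 mRNA features, log2 baselines uniform on
(4, 12). A fraction of miRNAs (default 2%, matching the order of magnitude
of reported DE fractions on such arrays) receives a ±1.5 log2 group shift
with random sign. Each planted pair's target gene follows its miRNA
linearly in log2 space, `gene = baseline + slope × (miRNA − its baseline) +
noise`, with slope −0.8 and Gaussian noise SD 0.3 by default — the simplest
mechanism that produces both the negative cross-sample correlation the
screen assumes and an opposite-direction group effect in the target. One
planted miRNA per gene by default, keeping recovery metrics unambiguous.
Seeding is hierarchical: one sub-stream per generation step, so enlarging
the mRNA panel does not perturb the miRNA draws.

What the generator does *not* emulate — and therefore what a green test
does not establish — includes batch and array effects, probe-level
artefacts, heavy-tailed or heteroscedastic noise, correlated co-regulation
among genes, missing values, and many-to-many regulation. The planted
world is linear-Gaussian by construction; recovery rates near 100% there
say the pipeline is wired correctly, not that real cohorts behave this
well. The headline counts of the motivating study (34 DE miRNAs, 394
target relationships, and so on) derive from its deposited arrays plus a
TargetScan snapshot and are not reproducible from synthetic data; the
package therefore validates against oracles, planted ground truth, and the
study's printed degree table instead.

## Validation-layer statistics

The qRT-PCR companion functions implement $2^{-\Delta\Delta Ct}$ relative
quantification (calibrated against the mean ΔCt of the control group by
default), Pearson and Spearman correlation with the t-transform p (Spearman
as Pearson on average ranks — figure legends in this literature name
Spearman while methods sections name Pearson, so the method is an explicit
argument with no silent default), pooled-variance two-sample t (Welch via a
flag) and one-way ANOVA. Two assay ratios are included verbatim from
laboratory practice: the WST proliferation "inhibition rate"
$(OD_{treated,t} - OD_{blank})/(OD_{untreated,0} - OD_{blank})$ — note this
reads as a viability ratio, and whether a published "inhibition rate"
intends $1 -$ this quantity is ambiguous; the formula is implemented as
printed and the ambiguity left to the caller — and the relative mean
fluorescence intensity (stain MFI / isotype MFI).

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  out_dir = "mirpath_run",
  simulate = simulation_config(repression_slope = -1, seed = 1),
  sensitivity = 1, false_pair_rate = 0, seed = 1)
res <- run_pipeline(cfg)
res$summary
```

On this seed the pipeline recovers all 50 planted relationships
(`n_relationships = 50` across 30 distinct miRNAs), flags the planted
pathway and GO sets, and reports 50 of 50 key targets — the behaviour the
acceptance suite asserts at ≥ 90% recall and precision.

## Known limitations

* The RVM fit assumes a single inverse-gamma variance population; strongly
  bimodal variance structure (e.g. mixed probe chemistries) would be
  shrunk towards one compromise prior.
* Pooled-sample correlation deliberately mixes the group contrast into the
  correlation; a within-group screening mode exists for users who want
  association beyond the case/control axis, but it is off by default.
* Identifiers are opaque case-sensitive strings; no attempt is made to
  reconcile miRNA naming conventions (miR-195 vs miR-195-5p) or gene
  aliases. Mixed conventions silently fail to intersect — by design, loudly
  documented here.
* GO structure is ignored (no parent-term propagation or elim-style
  decorrelation); sets are tested independently, as classical
  enrichment does.
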