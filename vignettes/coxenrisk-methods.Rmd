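---
title: "Cross-cell-type atherogenic risk prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cell-type atherogenic risk prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxenrisk)
```

# The problem

Subclinical atherosclerosis is hard to diagnose because patients are
asymptomatic and imaging is costly and restricted to patients who already
look high-risk. A blood-based transcriptomic screen is attractive: leukocyte
expression changes can precede plaque formation. `coxenrisk` implements a
complete analysis for this idea built around familial hypercholesterolemia
(FH) — a monogenic LDL-receptor defect with drastically elevated
atherosclerosis risk, more severe in homozygous than heterozygous carriers —
as the high-risk contrast. The pipeline asks two questions: can monocyte
expression biomarkers separate high-risk subjects from controls, and do
those biomarkers transfer to other leukocyte subsets (circulating T cells,
whole white blood cells, monocyte-derived macrophages)?

# The pipeline model

## Stage 1 — discovery

Each probe is tested with a pooled-variance two-sample *t*-test (high-risk
vs control), the classical equal-variance choice for two-group microarray
comparisons of this period; a Welch toggle exists (`var_equal = FALSE`).
Multiplicity is handled with Benjamini–Hochberg step-up *q*-values with the
null proportion fixed at 1 — deterministic and conservative; Storey-type
$\pi_0$ estimation is deliberately not used because it introduces a tuning
choice the analysis does not need. The retention rule is **inclusive**,
$q \le 0.01$: biomarker tables of this kind retain probes whose *q* prints
exactly at the threshold, and an inclusive comparison reproduces that
behaviour. Fold changes are reported on the signed linear scale
$r = 2^{\bar{x}_{high}-\bar{x}_{low}}$, returned as $-1/r$ when $r < 1$, so
$|FC| \ge 1$ always and the sign encodes direction. Zero-variance probes are
skipped with a warning rather than failing the run.

## Stage 2 — functional triage

Differential expression alone mixes disease biology with training-set
idiosyncrasy. The triage stage keeps flagged probes whose annotated function
falls in an atherosclerosis-relevant controlled vocabulary:
`r paste(atherosclerosis_categories(), collapse = "; ")`. The vocabulary
defaults to the categories that such curated biomarker panels actually carry
— note it includes immunological-disease annotations, which a narrower
reading ("inflammation, lipid and other metabolism, haematological
development") would miss. Proprietary pathway software is replaced by a
plain `probe_id / gene_symbol / category` table supplied by the user or the
simulator: the knowledge base becomes an explicit, versionable input instead
of an irreproducible black box. Whether a historical panel was further
hand-curated beyond category membership cannot be recovered; only category
filtering is implemented.

## Stage 3 — COXEN concordance selection

The co-expression extrapolation (COXEN) idea: a biomarker is worth carrying
into another cell type only if its *relations* to the other biomarkers are
preserved there. Concretely, for a panel of $g$ probes we compute the
$g \times g$ Spearman co-expression matrix in the training set and in the
test set (Spearman, because only the monotone relation is of interest and
intensities across platforms are not comparably scaled). Probe $i$'s
"fingerprint" is its row with the self-entry removed (length $g-1$); its
concordance is the Pearson correlation $r_i$ between its training and test
fingerprints, tested with the $t$ transform
$t = r\sqrt{(g-3)/(1-r^2)}$ on $df = g-3$ and selected when the **one-sided**
(upper-tail) $p < 0.001$, strict.

Numerical and design choices here:

* *Pearson on Spearman vectors*: the co-expression measure and the
  concordance measure play different roles; each uses the standard statistic
  for its role.
* *One-sided p*: a strongly **anti**-correlated fingerprint is a reversed
  co-expression pattern, not a preserved one; a two-sided rule would select
  it. The null per-probe selection rate at $\alpha$ is still exactly
  $\alpha$.
* *Self-correlations excluded*: the diagonal 1s would inflate every
  concordance spuriously.
* *No multiplicity adjustment*: the method is defined by a fixed per-gene
  threshold; adjusting would silently change panel sizes.
* *Small panels*: with $df = g-3$, a panel of ~25 probes cannot reach
  $p < 10^{-3}$ even at $r \approx 0.6$ — the minimum achievable p sits near
  the threshold. The pipeline therefore treats an empty (or sub-3-probe)
  selection for one test set as a warning and skips that set's COXEN
  predictor rather than aborting the whole report; `select_coxen_panel()`
  itself still errors, pointing at the $\alpha$ choice.
* Whether concordance should use all samples or controls only is
  undocumented in the source analyses; all samples of each set are used,
  which also lets class-driven co-expression count as genuine shared
  structure.

## Stage 4 — the risk predictor

Each dataset is standardized **within genes and within itself** (mean 0,
sd 1 across that set's samples, divisor $n-1$): the sets come from different
platforms and labs, so training statistics never transfer to a test set, and
any gene-wise affine distortion of a test set is absorbed exactly. PCA is
then taken over samples on the standardized panel (equivalently,
correlation PCA), keeping the **top 3 components regardless** of their
coverage — three components is part of the model definition; the observation
that they usually carry > 70% of the variance is checked and warned about,
not used as a selection rule. Loading signs are fixed (largest-magnitude
loading positive) so repeated fits are bit-identical.

On the 3-dimensional scores a two-class Gaussian LDA with pooled within-class
covariance and **equal priors** is fitted — equal priors implement "false
positives and false negatives weighted equally" and keep the score
independent of the training class balance; class-frequency priors are a
config option. The per-sample output is the Bayes posterior probability of
the high-risk class,
$P(\text{high}\mid x) = \text{logistic}(\delta_h(x) - \delta_l(x))$, a
continuous risk score in $[0,1]$. A numerically singular pooled covariance
(possible with 6-gene panels and few samples) is ridge-regularized with
$\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma)/3$ and a warning.

## Stage 5 — evaluation

Predicted scores are first compared between classes with the same pooled
*t*-test as discovery. The operating point is chosen on the ROC over
candidate cutoffs = observed score values plus a $+\infty$ sentinel,
classifying high when score $\ge$ cutoff — this grid attains every
achievable confusion table. The optimum maximizes the Youden index
(sensitivity + specificity − 1); ties break toward the higher-specificity
cutoff (fewer false alarms in a screening context; configurable by choosing
a cutoff directly). `confusion_at_cutoff()` reports the counts and
sensitivity/specificity/PPV/NPV/Youden; a zero-denominator rate is `NA` with
a warning, never silently 0. `metrics_from_rates()` inverts published
(sensitivity, specificity, group sizes) back to integer counts — useful for
auditing reported tables, and it exposes when a published row is not
internally consistent. WPGMA/McQuitty clustering (`wpgma_cluster()`, via
`hclust`) provides the heatmap-style view in which biomarker panels visibly
group patients; McQuitty linkage is robust to very uneven cluster sizes.

# The synthetic world

Real cohorts of this design cannot be redistributed, so the package
generates them. Expression for probe $g$, sample $s$, in one cell type:

$$x_{gs} = \mu_g + \textstyle\sum_k \lambda_{gk} f_{ks} + \delta_g z_s + \varepsilon_{gs}$$

with baselines $\mu_g \sim N(8, 1.5^2)$ (log2 intensity scale), $K = 3$
latent co-expression factors with loadings
$\lambda_{gk} \sim N(0, 0.08^2)$ and per-sample scores $f_{ks} \sim N(0,1)$,
a log2 risk effect $\delta_g$ applied to high-risk samples
($z_s \in \{0, 1\}$, scaled to 1.8 for homozygous-FH samples — homozygous
disease is clinically far more severe, and only the ordering of effects
matters here), and noise $\varepsilon \sim N(0, 0.18^2)$.

**Concordance dial.** A configurable fraction of the differential probes
(default 0.5) is *concordant*: they keep both their loadings $\lambda$ and
their effect $\delta$ in every cell type. Discordant probes get both
redrawn, independently, in each non-training cell type. This is the
package's concrete realization of "concordantly expressed genes", and the
effect redraw is deliberate: with the risk effect shared everywhere, the
class signal dominates every differential probe's co-expression fingerprint
and *all* of them look concordant — the dial would not dial. Redrawing
$\delta$ also matches biology: a monocyte biomarker need not be regulated
the same way, or at all, in T cells.

**Default magnitudes** were fixed from an a-priori power calculation, not
tuned to tests. Effects $|\delta| \in [\log_2 1.1, \log_2 1.9]$ — the
published fold-change range of curated atherosclerosis biomarker panels.
Total per-probe standard deviation
$\sqrt{0.18^2 + 3 \cdot 0.08^2} \approx 0.23$ makes the standardized effect
of a mid-range probe $\approx 2$–3, which with 10 vs 13 samples and a BH
threshold near $p \sim 4\times10^{-4}$ gives per-probe power high enough to
recover the bulk of planted effects at $q \le 0.01$, while small-end effects
(FC 1.1–1.2) stay genuinely hard — as they are in practice. 100 of 2000
probes are differential (5%, desk-scale stand-in for 363 of ~54k). The
sample designs copy the emulated cohorts exactly: monocytes 3+7+13, T cells
the same 23 subjects, whole blood 5+5, macrophages 14+14.

**What the generator does not emulate** — and hence what a green test does
not establish: probe-level array artifacts, batch and platform effects
beyond gene-wise affine distortion, heavy-tailed or intensity-dependent
noise, correlated effect directions within pathways, and any real biology of
the annotated categories (annotations are assigned at random within the
vocabulary). Tests on this world validate the *machinery* — calibration,
recovery, transfer — not clinical performance.

A consequence of the latent factors worth knowing: because a factor's scores
can correlate with the class split by chance in 23 samples, probes loading
on that factor can show planted-size spurious effects, so a discovery run on
a *non-null* cohort can flag more than the nominal share of false probes in
an unlucky seed. Marginally each null test is exact (factor scores are iid
per sample), so null-cohort FDR calibration holds in expectation — which is
what the calibration suite checks, over 50 seeds.

# Interfaces

Expression matrices, metadata and annotations are plain UTF-8 TSVs (GEO
series-matrix spirit; no SOFT/MINiML or CEL handling — the loader assumes
values are already normalized and log2-scaled, since upstream preprocessing
of the emulated datasets is not documented and is out of scope). Trained
predictors serialize to JSON with full provenance and reproduce their
posteriors on reload. `run_pipeline()` writes per-stage TSV artifacts, model
JSONs, a manifest, and an evaluation report formatted the way such tables
are published (rates in percent to 1 decimal, Youden to 2).

Probe order after cross-platform intersection is lexicographic — an
arbitrary but fixed convention that pins PCA loading signs and makes every
downstream artifact reproducible byte-for-byte.

# Known limitations

* Pooled-variance *t*-tests and non-moderated statistics are faithful to
  the implemented analysis but are not the modern method of choice for
  small-$n$ microarray discovery (empirical-Bayes moderation would be).
* The concordance *t*-test treats a probe's $g-1$ fingerprint entries as
  independent observations; they share the underlying samples, so the
  nominal $df = g-3$ is optimistic. The null calibration suite shows the
  practical selection rate still sits at $\alpha$ for independent datasets.
* With panels below ~30 probes the $p < 0.001$ concordance rule is
  effectively unattainable (see above); users with small panels should
  revisit `coxen_alpha`.
* Posterior scores are not calibrated probabilities in any clinical sense;
  they are discriminant scores mapped through a Gaussian model fitted on a
  handful of samples.
* Evaluation picks the Youden cutoff on the same test set it reports
  metrics for, as the emulated analysis did; honest prospective performance
  would require a third, untouched cohort.
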