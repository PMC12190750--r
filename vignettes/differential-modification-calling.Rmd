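---
title: "Calling differential RNA modifications from bedMethyl counts"
author: "dmscall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential RNA modifications from bedMethyl counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscall)
```

# The problem

Direct RNA nanopore sequencing reads native RNA molecules, so chemical
modifications (m6A, m5C, inosine, pseudouridine) survive into the signal and
can be called per read and per position by modification-aware basecalling.
Pileup tools summarize these calls into bedMethyl tables: for every
transcript position and modification code, the number of reads called
modified and canonical in each sample. `dmscall` takes such tables for a
two-condition experiment (here: pancreatic beta-cell lines under low and
high glucose) and asks, site by site, whether the *fraction of modified
reads* changes with condition — a differentially modified site (DMS).

Two features of this data type drive the design. First, modification
callers produce systematic false positives; an in vitro transcribed (IVT)
library — chemically modification-free by construction — exposes them,
because any apparent modification signal in IVT reads is caller error.
Second, experiments span multiple cell lines with few biological replicates
each, so per-line evidence must be combined while guarding against both
single-replicate artifacts and line-specific (non-reproducible) effects.

# The model

## Site screening

A site enters testing only if, across the native replicates,

* mean total reads (modified + canonical) $\ge$ 20,
* modification proportion $\ge$ 5%,

and its IVT modification proportion is strictly below 5% (sites never
observed in IVT pass this rule: an unobserved site cannot be tested against
the control). Proportions are computed from pooled counts by default
(`prop_mode = "pooled"`), which weights replicates by depth and is stabler
at low coverage than the mean of per-replicate ratios; the latter is
available as a sensitivity mode. Failures are attributed to the first rule
violated, in the order coverage, native proportion, IVT — the order in
which the rules restrict the universe.

## Per-line test

Within each cell line the per-site counts are modeled by a binomial GLM
with logit link,

$$\mathrm{cbind}(m_i, c_i) \sim \mathrm{condition}, \qquad
\log\frac{p_i}{1-p_i} = \beta_0 + \beta_1 \, \mathbf{1}[\text{high}],$$

fit by iteratively reweighted least squares. $\beta_1$ is the log-odds
difference in modification between conditions (positive = more modified
under high glucose); its Wald $P$-value uses the normal reference. For this
two-group design the MLE coincides with the pooled log-odds ratio,
$\hat\beta_1 = \log\frac{M_1/C_1}{M_0/C_0}$ with standard error
$\sqrt{1/M_1 + 1/C_1 + 1/M_0 + 1/C_0}$ — the closed form the test suite
uses as an independent oracle.

Influence is screened with Cook's distance per sample,
$D_i = r_i^2 h_i / (\varphi\, p\, (1-h_i)^2)$ (Pearson residual $r_i$,
leverage $h_i$ from the weighted hat matrix at convergence, dispersion
$\varphi = 1$, $p = 2$ coefficients), referred to an $F(p,\, n-p)$
distribution. A site whose minimum Cook's $P$-value falls below 0.05 is
*pruned*: the site (not the sample) leaves the downstream analysis, so a
single aberrant replicate cannot manufacture a discovery.

## Combining lines

Per-line estimates are pooled with the inverse-variance fixed-effects
model: weights $w_i = 1/\mathrm{se}_i^2$, pooled effect
$\hat\beta = \sum w_i b_i / \sum w_i$, $\mathrm{se} = (\sum w_i)^{-1/2}$.
Cochran's $Q = \sum w_i (b_i - \hat\beta)^2$ on $k-1$ degrees of freedom
flags heterogeneity; sites with $P_Q < 0.05$ are removed *before* multiple
testing, because a site whose effect is not shared across lines is not the
reproducible biology the caller targets (and should not inflate the BH
denominator). Benjamini–Hochberg is applied within each modification code —
discoveries are reported per modification — with a global-pool switch
(`bh_scope = "global"`). Sites testable in only one line enter as $k = 1$
"meta-analyses" (identical to the single study) by default;
`both_lines_only = TRUE` restricts to sites tested in every line.

## Effect-size shrinkage

Raw log-odds estimates at shallow sites are noisy and overstate effect
magnitudes. For ranking and visualization the package fits an
empirical-Bayes model with a zero-centered normal mixture prior: a point
mass at zero plus normal components on a $\sqrt2$-geometric grid of
standard deviations from $\min(\mathrm{se})/10$ to
$2\sqrt{\max(\hat\beta^2 - \mathrm{se}^2, 0)}$. Mixture weights maximize
the marginal likelihood with a Dirichlet-style pseudo-count of 10 on the
null weight (the conservative convention for this estimator; set
`penalty_null = 1` to disable). Because the likelihood is concave in the
weights, EM converges to the global optimum from any start — the test
suite's independently written, multi-restart EM must and does agree.
Posterior means multiply each estimate by component-specific factors
$\sigma_k^2 / (\sigma_k^2 + \mathrm{se}_j^2) \in [0, 1)$, so shrunken
effects never exceed the raw estimate in magnitude nor cross zero. Only
posterior means are produced; FDR control remains BH on the meta-analysis
$P$-values.

## Enrichment and the stimulation index

Genes carrying at least one DMS are tested for over-representation of a
user-supplied gene set (e.g. type-2-diabetes effector genes) with the
upper-tail hypergeometric test, against the universe of genes carrying at
least one *tested* site for that modification — genes that never had a
testable site cannot be discoveries, so they do not belong in the
denominator. BH is applied jointly across (modification, set) pairs.

The glucose-stimulated insulin secretion index (mean insulin under high
glucose over mean under low) gets a Fieller confidence interval — exact for
a ratio of independent normal means, with the documented unbounded branch
when the denominator mean is not significantly nonzero — and a
$P$-value from the two-sample $t$ statistic for "index = 1" (equivalently,
equal means), on pooled degrees of freedom $n_H + n_L - 2$ by default
(Welch via `df = "welch"`).

# The synthetic experiment generator

`simulate_experiment()` produces complete, parseable experiments with
ground truth, so every stage is testable without sequencing data. It
emulates:

* the study's replicate structure — two cell lines with 3 and 4 biological
  replicates, each cultured under both conditions, plus one IVT sample per
  line and condition;
* per-site coverage as negative binomial (mean 60, size 5 by default) —
  nanopore per-site depth is strongly overdispersed, and this is the main
  stress the depth thresholds face;
* genuinely modified sites with baseline proportions from Beta(2, 8)
  truncated to $\ge$ 0.05, condition effects of $|\Delta\text{logit}| =
  1.5$ (random sign) on 10% of sites, and line-specific effects on 2%
  (each line draws its own effect — the heterogeneity filter's target);
* caller artifacts on 5% of sites: a spurious proportion drawn from
  Beta(2, 8) appears in native *and* IVT samples, with no condition effect;
  all other sites show a Beta(1, 99) basecall error floor (mean 1%) in IVT;
* injectable outlier replicates whose low/high proportions are swapped —
  the failure mode Cook's pruning exists to catch.

Everything derives from one integer seed through R's default Mersenne–
Twister stream; runs are byte-identical across repeats.

What it does **not** emulate: positional correlation along transcripts,
between-site dependence, mappability/strand artifacts, overdispersion of
counts beyond binomial at fixed $p$ (e.g. within-replicate cell
heterogeneity), or modification co-occurrence on reads. Passing
calibration on these simulations therefore demonstrates correctness of the
statistical machinery under its own assumptions, not robustness to every
failure mode of real nanopore data.

# Numerical choices

* IRLS convergence at deviance change $< 10^{-12}$, 100 iterations; the
  Wald covariance is evaluated from the Fisher information at the
  *converged* coefficients (the last half-step's weights would cost ~1e-8
  relative accuracy against the closed form).
* Quasi-complete separation (a pooled modified or canonical count of zero
  in either condition) has no finite MLE: flagged non-estimable and
  excluded, with no continuity correction — a site that cannot contribute a
  finite (estimate, SE) pair cannot enter the meta-analysis.
* A condition with zero total coverage makes the site untestable in that
  line (`tested = FALSE`), not an error.
* EM stops when the penalized log-likelihood gains less than `tol = 1e-7`
  (cap 5000 iterations) and *errors* if it ever decreases beyond numerical
  noise — a monotonicity guard against implementation bugs.
* Proportion thresholds follow their wording: "at least" 5%/20 reads is
  $\ge$, "less than" 5% in IVT is strict $<$.
* BH q-values inherit `p.adjust`'s step-up with monotonicity enforcement;
  missing $P$-values propagate as NA and do not count toward the number of
  tests.

# Test and acceptance problem sizes

The simulation-based checks run at: 5,000 sites for null calibration
(depth mean 60); 10 seeds of 1,500 sites for FDR/power and effect recovery
(depth mean 100, 10% true DMS); 3,000 sites for the artifact screen; 2,000
replicates for Fieller coverage; 2,000 observations for the shrinkage null
weight. These sizes give Monte-Carlo error comfortably inside the asserted
bands while keeping the default suite quick on a laptop.

# Known limitations

* With three replicates per condition and strongly imbalanced coverage, a
  single swapped replicate can be partially *masked* in Cook's distance: a
  much deeper clean replicate may carry the largest distance. The site is
  still usually pruned (some sample's Cook's $P < 0.05$), but attribution
  of the maximal distance to the true outlier is only near-certain when
  depths are comparable.
* The binomial likelihood has no extra-binomial dispersion; replicate
  heterogeneity beyond binomial noise is only partially absorbed by the
  heterogeneity filter.
* Fixed-effects meta-analysis presumes one shared effect; the Cochran's Q
  filter discards, rather than models, sites violating this.
* One-line sites carry $k = 1$ through the default pipeline; their
  evidence rests on a single line and no heterogeneity check is possible.
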