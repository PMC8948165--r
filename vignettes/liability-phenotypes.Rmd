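---
title: "Liability phenotypes from family history and age of onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability phenotypes from family history and age of onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltfhpp)
```

## The model

Under the liability threshold model every person carries a latent standard
normal liability $\ell$ and is a case exactly when $\ell \ge T$, where the
threshold $T$ satisfies $P(\ell \ge T) = K$ for the disease prevalence $K$.
The liability decomposes into independent genetic and environmental parts,
$\ell = \ell_g + \ell_e$ with $\ell_g \sim N(0, h^2)$ and
$\ell_e \sim N(0, 1 - h^2)$, where $h^2$ is the liability-scale
heritability.

For a genotyped index individual with relatives, the vector
$(\ell_g, \ell_o, \ell_{r_1}, \ell_{r_2}, \dots)$ — the index's genetic
component, their full liability, and the relatives' full liabilities — is
multivariate normal.  Covariances follow from the coefficient of
relationship $r$ (0.5 for parents and full siblings):
$\mathrm{Cov}(\ell_g, \ell_o) = h^2$,
$\mathrm{Cov}(\ell_g, \ell_r) = \mathrm{Cov}(\ell_o, \ell_r) = r h^2$,
father and mother are unrelated, and sibling-sibling and parent-sibling
covariances are $h^2/2$.  Environmental components are independent between
family members; this is a model assumption and is not configurable.
`liability_covariance()` builds this matrix for any number of siblings.

The phenotype this package produces is the posterior mean genetic
liability $E[\ell_g \mid Z]$ of the index individual given everyone's
status information $Z$, used as a continuous outcome in GWAS.

## Age-dependent thresholds

The extension over the pure case-control model is that each person's
threshold is *personalized*.  The cumulative incidence of the disorder in
the person's stratum (sex, birth year) is an increasing function of age,
so the implied threshold
$T(\text{age}) = \Phi^{-1}(1 - \mathrm{CIF}(\text{age}))$ decreases with
age:

* a **control** of age $a$ has survived their risk up to $a$ only, so their
  liability is constrained to $(-\infty, T(a))$ — an old control is much
  stronger evidence of low liability than a young one;
* a **case with age of onset** $a$ was diagnosed exactly when the falling
  threshold crossed their liability, so their full liability is *fixed* at
  $T(a)$ — early onset implies high liability;
* a **case without onset information** is constrained to
  $[T(a_{\text{censoring}}), \infty)$;
* a person with **unknown status** is unconstrained, and relatives with
  unknown status are excluded from the family model entirely;
* a person with known status but **no age** gets the stratum's lifetime
  cumulative incidence — the group-threshold (LT-FH style) behaviour.

With every age and onset missing, the constraints reduce exactly to the
group-threshold model, and the estimates collapse to LT-FH estimates (this
degeneracy is asserted in the test suite).

Viewed over a short age interval, the model is a survival model: the
probability of onset in $(t, t+dt)$ given no onset by $t$ is
$1 - \Phi\!\big(\tfrac{T(t+dt)-g}{\sqrt{1-h^2}}\big) \big/
\Phi\!\big(\tfrac{T(t)-g}{\sqrt{1-h^2}}\big)$, implemented in
`hazard_probability()`; `cox_hazard_probability()` provides the
constant-baseline proportional-hazards analogue $dt\,\alpha\,e^{g}$ for
side-by-side plots.  The printed form of the interval probability is
implemented as $[A-B]/A = 1 - B/A$ of its defining decomposition, the
algebraically forced reading.

## Cumulative incidence input

`build_incidence_surface()` ingests a long table of cumulative incidence by
sex, birth year and age.  Conventions, chosen to match yearly register
semantics:

* **step interpolation** (last observation carried forward) between
  tabulated ages; linear interpolation is available behind a flag and is
  used when tabulating smooth analytic curves
  (`logistic_incidence_surface()`);
* birth years outside the table **clamp to the nearest tabulated year**
  with a warning — approximate strata are the norm (e.g. assuming parents
  are 25 years older than their child);
* **unknown sex averages** the male and female values unweighted;
* each person's *own* stratum is always used; relatives are never given
  the index's stratum, and each sibling is a separate record;
* incidence proportions are clamped to $[10^{-12}, 1-10^{-12}]$ before the
  quantile transform so near-certain outcomes (late-life mortality) keep
  finite thresholds.

`aalen_johansen_cif()` estimates cumulative incidence from raw
time-to-event records under competing risks (death, emigration) via the
multi-state Aalen-Johansen estimator; tied times follow the standard
convention (events use the risk set just before the tied time, censorings
leave afterwards).

## Posterior computation

Fixed liabilities (cases with onset) are removed by exact Gaussian
conditioning (`condition_on_fixed()`); sampling error is reserved for the
coordinates that genuinely need integration.  The remaining
interval-constrained coordinates are integrated by a Gibbs sampler over
the truncated multivariate normal (`gibbs_truncated_mvn()`, C++ core):
coordinates are updated in a fixed order, each from its univariate
conditional truncated normal.  Unconstrained relatives are dropped from the
sampling problem since they contribute no information.  If every relative
is fixed, the posterior mean is returned analytically with `n_samples = 0`.

Numerical choices:

* truncated normal draws use inverse-CDF sampling on the central range and
  a shifted-exponential rejection algorithm beyond 4 standard deviations,
  which remains exact past 8 sd where the naive inverse CDF underflows
  (relevant for thresholds from near-one cumulative mortality);
* the stopping rule retains batches of 1,000 samples after 200 burn-in
  sweeps and stops when the batch-means standard error of the tracked mean
  reaches `sem_tol` (default 0.01) or `max_samples` (default $10^5$);
  because the batch-means SE estimate is noisy with few batches, at least
  five batches and two consecutive passing checks are required — without
  this, runs can stop after two batches with a badly optimistic SE;
* each family's chain is seeded from the master seed and the family id, so
  results are reproducible bit-for-bit and independent of processing order
  (families are mutually independent and can be processed in any order or
  in parallel).

Default `sem_tol = 0.01` makes Monte Carlo noise negligible against the
between-person spread of posterior means (standard deviation around
0.2-0.5); mass simulation experiments in the test suite relax it to 0.05,
which adds variance two orders of magnitude below the phenotype variance.

The package deliberately does not implement the "at least one affected
sibling" aggregated sibling status of the original group-threshold
formulation: per-sibling records are required.  It also does not filter
related genotyped individuals; as in the underlying method, users should
restrict to individuals without shared family members before GWAS, since
shared relatives correlate the phenotypes beyond genetic similarity.

## Comparison phenotypes

* **case-control**: the index's status, tested with the Cochran-Armitage
  trend test (`case_control_test()`), the standard 1-df genotype-trend
  chi-squared; with covariates the linear-regression score test is used
  instead;
* **GWAX** (`gwax_phenotype()`): proxy-case status — 1 if the index or any
  family member is a case;
* **LT-FH** (`ltfh_liability()`): posterior mean genetic liability with one
  threshold for the index and siblings and another for parents, intervals
  only;
* **LT-FH++** (`estimate_liability()`): the personalized-threshold
  posterior mean described above.

Continuous phenotypes are tested by per-SNP ordinary least squares
(`linear_gwas()`).  `gwas_power()` counts causal variants with $p$ strictly
below the threshold; `compare_chisq()` regresses one method's chi-squared
statistics through the origin on another's over a common variant selection
($p < 5\times10^{-6}$ for at least one method, by default) and reports the
slope minus one as the relative effective-sample-size gain.

## The simulation framework

`simulate_cohort()` generates the benchmark's study conditions: families
with two parents and 0-2 siblings; allele frequencies uniform on
$(0.01, 0.49)$; parents Binomial(2, AF); children the parental average
with half-integers rounded up or down with equal probability; causal
effects $\beta_j \sim N(0, h^2/C)$ on standardized genotypes; liabilities
$\ell = \ell_g + e$; sex-specific lifetime prevalences with a 4:1
male:female ratio (8%/2% at overall $K=5\%$, doubled at 10%); onset ages
from inverting the logistic cumulative incidence
$L/(1+e^{-k(x-x_0)})$ with $k = 1/8$, $x_0 = 60$ at the liability's
upper-tail quantile; control index/sibling ages uniform on (10, 60) and
parent ages the child's plus uniform (20, 35); optional ascertainment by
downsampling controls to a 50/50 case-control split.  Defaults are
100,000 families and 100,000 SNPs with 1,000 causal.

Design choices worth knowing about:

* **Exact case counts.**  Within each sex the top $K_{\text{sex}} \cdot n$
  liabilities are cases, fixing prevalence exactly; index individuals get
  an exactly balanced sex split so the ascertained sample size is exact
  (10,000 at $K=5\%$ from 100,000 families).  High-liability individuals
  whose implied onset exceeds their age are *not* reassigned to controls.
* **Onset boundary.**  A case at the empirical threshold boundary can have
  a liability quantile at or above the lifetime asymptote $L$; the
  quantile is clamped just below $L$ (factor $1-10^{-6}$), yielding a very
  late onset rather than an error, and onsets inverting below age zero are
  set to zero.
* **Inheritance-scheme moments.**  The parental-average-with-rounding rule
  preserves allele frequencies but leaves the child's genotype variance at
  $pq + (1-(1-2p)^4)/8$, below the Hardy-Weinberg $2pq$.  On
  population-AF-standardized genotypes the index's genetic-liability
  variance is therefore about $0.78\,h^2$ (parents' is exactly $h^2$) and
  the parent-offspring genetic correlation about 0.56 rather than 0.5.
  The tests assert these closed-form consequences of the scheme.
* **No birth-year effects** and no linkage disequilibrium, assortative
  mating, or environmental covariance: the generator reproduces the
  benchmark's generative model, not real register data.  Passing tests
  demonstrate correctness under this model; they do not certify behaviour
  under model misspecifications real data may carry (beyond the
  heritability/prevalence misspecifications that are tested explicitly).

## Problem sizes used in the test suite

The full-scale benchmark (100,000 families, 10 replicates) establishes
relative power gains of roughly 18%/15% for the personalized-threshold
phenotype over the group-threshold one under ascertainment at 5%/10%
prevalence.  The packaged test suite runs a reduced-scale qualitative
version chosen a priori by a power calculation: 6,000 families before
ascertainment, 10% prevalence, 25 causal SNPs carrying $h^2 = 0.5$
(per-SNP non-centrality around 25-30 after ascertainment, so genome-wide
power is measurably away from both 0 and 1), averaged over five seeds.  At
this scale the suite asserts the ordering LT-FH++ $\ge$ LT-FH $\ge$
case-control in mean power and the robustness of power to misspecified
heritability ($h^2 \in \{0.25, 0.75\}$ when the truth is 0.5) and
prevalence (halved/doubled); the quantitative 18%/15% gains are a
full-scale statement and are not asserted at reduced scale.  Calibration
uses $10^4$ null SNPs against phenotypes from 1,500 families; sampler
correctness is checked against a rejection-sampling oracle on 20 random
family configurations and against closed-form truncated-normal means.

## Known limitations

* Only the posterior *mean* is reported — no credible intervals.
* Supported relatives are parents and full siblings ($r = 0.5$);
  half-siblings and grandparents are out of scope.
* Heritability is an input, never estimated; robustness to its
  misspecification is a tested property, not a license to guess wildly.
* The categorical-risk-factor extension (stratifying incidence by, say,
  smoking status) can be emulated by extra strata columns but is untested
  against any published result.
* Mixed-model association on real data is delegated to external tools via
  the PLINK phenotype export (`write_plink_phenotype()`).
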