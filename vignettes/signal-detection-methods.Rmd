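---
title: "Disproportionality and time-to-onset signal detection: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality and time-to-onset signal detection: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxsignal)
library(dplyr)
```

This vignette is the package's account of the science it implements: the
two detection models and their assumptions, the parameters that matter and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open.  It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The data model

The unit of analysis is one spontaneous vaccine–event mention: a report row
carries a report id, receipt date, suspected vaccine, coded adverse-event
term, sex, age, region, reporting year (always derived from the receipt
date) and a time-to-onset (TTO) — the number of days between immunisation
and event onset, frequently missing in real pharmacovigilance data.  A case
reporting several events contributes one row per event; de-duplication
across reports is out of scope.  Unknown sex/age/region are `NA` in the
tibble and become a real `"UNK"` stratum level, never an exclusion:
dropping such rows would break count conservation between stratified and
unstratified runs.

## The gamma Poisson shrinker

Under independence of vaccine and event within each stratum, the expected
count of a pair is the Mantel–Haenszel sum
$E(v,e) = \sum_s n_{v \cdot s}\, n_{\cdot e s} / n_{\cdot\cdot s}$ over
strata with positive totals — including strata where the vaccine and event
occur but never co-occur.  Stratification absorbs confounding by
demographic and secular reporting-rate differences; the grid sweeps all 16
subsets of sex, age, region and year.

The relative reporting ratio $\lambda = \mu/E$ receives the two-component
gamma mixture prior $P\,\Gamma(\alpha_1,\beta_1) +
(1-P)\,\Gamma(\alpha_2,\beta_2)$, fitted once per stratification by
maximising the marginal likelihood of all reported pairs (the background is
the entire database, all vaccines).  Marginally each component makes $N$
negative binomial, so the objective is a 5-parameter NB-mixture likelihood.
Numerical choices:

* optimisation on $\log$ shapes/rates and $\mathrm{logit}\,P$, so
  positivity and the unit interval are enforced by construction;
* Nelder–Mead followed by a BFGS polish, convergence when the
  log-likelihood improves by less than $10^{-8}$; non-convergence is a
  classed error carrying the best-so-far parameters;
* starting values $(0.2, 0.1, 2.0, 4.0, 1/3)$ — the conventional defaults
  for this model family;
* only observed pairs ($N \ge 1$) enter the fit; unobserved cells are never
  enumerated, and the evaluation universe is likewise the reported pairs.

The posterior is the mixture $Q\,\Gamma(\alpha_1+N,\beta_1+E) +
(1-Q)\,\Gamma(\alpha_2+N,\beta_2+E)$ with $Q$ the posterior component
weight.  EBGM $= \exp E[\ln\lambda]$ via the digamma function; EB05/EB95
are found by root-finding on the mixture CDF bracketed by the component
quantiles (CDF solved to well below $10^{-6}$ absolute; the test suite
verifies the bounds by independent quadrature).  A pair is flagged when
EB05 **strictly** exceeds the cut-off: a pair sitting exactly on the
threshold is not a signal, consistent with cut-off semantics of
"exceeding" a value.  The prior is refitted for each stratification
(because $E$ changes with it), not per threshold; re-thresholding a fit is
free, which is what makes the 21-threshold sweep cheap.  A prefit prior can
be passed to `run_mgps()` to emulate a single shared prior instead.

On a database that is truly null apart from sampling noise, the fitted
prior collapses towards a point mass at $\lambda = 1$ and low EB05
cut-offs flag nearly everything.  That is faithful behaviour of the
empirical-Bayes model, and it is why low-threshold configurations score a
very poor PPV on the synthetic benchmark; real safety databases carry
pair-level heterogeneity that spreads the prior out.

## The time-to-onset detector

The premise is that the database-wide TTO pattern is dominated by reporting
bias and noise (the later an event occurs after immunisation, the less
likely it is reported), so a pair whose delays deviate from that shared
pattern is interesting *regardless of its reporting volume*.  For a pair
and a window $[0, T]$ days (both ends included, $T \in \{30, 60, 90\}$)
the in-window, non-missing delays are compared against two backgrounds:
same vaccine/other events, and same event/other vaccines (the vaccine of
interest excluded).  The target pair's own reports appear in neither
background.

The test statistic is the two-sample Kolmogorov–Smirnov
$D = \sup_t |F_x(t) - F_y(t)|$, evaluated at every pooled observed value —
the standard ties convention, since integer-day delays are heavily tied.
The p-value defaults to the asymptotic Kolmogorov tail of
$D\sqrt{n_x n_y/(n_x+n_y)}$, which is conservative under ties; an exact
conditional p-value (via `stats::psmirnov`) is available when
$n_x n_y \le 10^4$.  Conservatism suits a screening test: the dual-test
AND rule (both p-values $< \alpha$, each at raw level $\alpha$, no
multiplicity correction across pairs) already keeps the null flag rate
well under $\alpha$, which the acceptance tests measure.  The benchmark
sweeps raw alpha levels, so false-discovery control is the benchmark's
job, not the test's.

`min_target` defaults to 1 — no hard minimum sample size is imposed, so
small pairs are tested and simply tend not to reach significance.  The
empirical observation that about ten in-window delays are needed before
this detector can fire is exposed as the optional guard rather than a
hard-coded rule.  Pairs with no in-window data or an empty background get
an explicit status (`INSUFFICIENT_TARGET` / `INSUFFICIENT_BACKGROUND`) and
are never flagged; in ROC sweeps such pairs are permanently unflaggable,
which truncates attainable sensitivity below 1 — a structural property of
the method, not an artefact.

## The benchmarking protocol

Every reported pair of a vaccine covered by the gold standard is classified
TP/FP/TN/FN against the label set; vaccines absent from the gold standard
are excluded (not counted as negatives), and conservation
TP+FP+TN+FN+excluded = universe is tested.  The primary measure is the
per-vaccine PPV rank: within each vaccine, algorithms are ranked by
descending PPV with midranks for ties — midranks are the only assignment
that produces the fractional median ranks the protocol reports — and each
algorithm is summarised by the median and standard deviation of its ranks
across vaccines.  An algorithm that flags nothing for a vaccine has
undefined PPV there; that cell is dropped from its rank vector rather than
imputed, since imputation would fabricate an ordering.  ROC curves sweep
EB05 from 0 to 10 by 0.1 and the p-value threshold from 0 to 1 by 0.01.

Time-to-detection replays the database in receipt-date order and re-runs
the detector after each arrival; the result is the number of reports
received, and the number actually *used*, at first detection.  "Used"
counts every received report for the shrinker but only in-window,
non-missing-TTO reports for the TTO detector; whether the used count covers
the target pair plus both backgrounds (default) or the target pair only is
configurable, because the method definition pins down only the missingness
rule.  Full per-step recomputation is the default (correctness over
speed); a coarse mode re-evaluates only when the target pair itself gains
a report, and the suite asserts first-detection equivalence on the
reference fixture — equivalence is not guaranteed in general, since the
prior and backgrounds can drift between target arrivals.

## The synthetic-data generator

`simulate_database()` emulates the structure both detectors assume:

* skewed vaccine and event reporting propensities (gamma-distributed
  marginals), pair counts Poisson around
  `n_reports x p_v x p_e x rel_rate`;
* per-vaccine demographic profiles (infant through elderly age archetypes,
  female fraction, reporting-year windows) tilted by multiplicative
  stratum rate effects, so stratification has real confounding to absorb;
* background onset delays from a geometric distribution with mean 10 days
  truncated at 365 — the reporting-bias decay premise, keeping most mass
  inside all three windows;
* per-vaccine TTO missingness drawn from [0.12, 0.52], the range observed
  across heterogeneous vaccine portfolios;
* injected signals of four profiles: pure disproportionality (default
  relative rate 10), clustered onset (discretised log-normal, mode 2 days,
  sdlog 0.5), and the two TTO blind spots — delays uniform on 91–365 days
  ("lack-of-efficacy-like" long-onset events) and delays always missing.
  The truth table is emitted as a gold standard so the evaluation module
  consumes simulator output unchanged.

Defaults are 20 vaccines x 250 events x 50,000 expected reports: large
enough that pair-level counts and background TTO pools resemble a working
safety database, small enough that a full grid run stays interactive.  The
deterministic `table_like_fixture()` (8 vaccines, ~2,000 reports,
per-vaccine missingness spanning 0.12–0.52) is the standard test fixture.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: duplicate and follow-up reports, MedDRA coding
granularity and hierarchy, secular reporting surges, correlated
multi-event cases (each simulated row has its own id), and pair-level
overdispersion beyond the injected signals.  The last point matters most:
real databases are overdispersed even off-signal, so absolute flag rates
and PPVs here characterise the method under clean conditions, not expected
field performance.

## Choices made where the design was open

* **Age bins** default to [0,2), [2,12), [12,18), [18,46), [46,66),
  [66,inf) — separating infant, child, adolescent and adult vaccine target
  populations — and are configurable; no canonical binning exists for this
  protocol.
* **Region coding** is whatever code the file carries; no geographic
  dictionary is bundled.
* **One prior per stratification** rather than one global prior: expected
  counts change with the stratification, so the empirical-Bayes background
  should too.  Passing a prefit `prior=` covers the alternative.
* **Exact vs asymptotic KS p-values**: both implemented, asymptotic
  default (conservative under ties and scale-free across the grid).
* **Undefined PPV handling** in ranking: drop, don't impute (above).
* **Problem sizes in tests**: oracle comparisons run on 1,000 small KS
  fixtures, 100 posterior-quantile triples, a 50,000-pair prior recovery
  and 50,000-report calibration/recovery databases — sizes chosen so each
  acceptance property is measured with comfortable statistical resolution
  while a full suite run stays in the tens of seconds.

## Known limitations

Higher-order itemsets (beyond pairs) are not implemented; the shrinker
offers no regression-based confounder adjustment beyond stratification;
the TTO detector is blind to sub-day onset precision and to any signal
whose delays are out-of-window or unrecorded — by design, that blindness
is part of what the benchmark measures.  The gold-standard mechanism is a
file format and a lookup rule; curating a medically meaningful label set
is the user's responsibility.
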