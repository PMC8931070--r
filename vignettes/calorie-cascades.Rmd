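---
title: "Calorie cascades on trade networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calorie cascades on trade networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodcascade)
```

## The problem

International food trade decouples what countries eat from what they
grow.  That cuts both ways: trade lets a country hedge a bad domestic
harvest by buying abroad, and it also transmits other countries' bad
harvests into its own food supply.  `foodcascade` studies this tension
with a mechanistic simulation: a directed network whose nodes are
countries and whose edge weights are the calories (kcal/year) embedded
in bilateral food exports, on which a production shock propagates as a
cascade of export cuts and import surges.  The package then measures,
per country, exposure to foreign shocks, the ability to pass domestic
shocks on (hedging), the reserve stock needed to ride out almost all
simulated shocks, and two vulnerability scores, and fits regressions
linking these outcomes to each country's position in the network.

## Baseline accounting

Each country carries GDP, population and a domestic food supply
(kcal/year, the food-balance-sheet quantity).  Exports are row sums of
the weight matrix, imports are column sums, and production is derived
as `supply + exports - imports`.  Baseline demand, defined as
`production + imports - exports`, therefore equals supply identically --
a deliberate closure of the accounts that makes "demand deficit" mean
exactly "calories missing relative to the pre-shock food supply".
Zero-weight edges are treated as absent; self-loops and negative
weights are rejected; a country whose imports exceed supply plus
exports (negative derived production) is rejected by name.

All internal accounting is in kcal/year.  Per-capita daily quantities
divide by population times `days_per_year` (default 365, a
configuration constant).

## The cascade

A shock removes a fraction (default 30%) of one country's production,
leaving it a demand deficit equal to the lost calories.  The origin
compensates through two channels controlled by `alpha`:

* export cuts (share `alpha`): outgoing flows are reduced until
  `alpha * shock` has been shed or every out-edge is exhausted;
* import increases (share `1 - alpha`): inbound flows rise in
  proportion to the calories each supplier already ships, and the
  suppliers acquire the corresponding deficit themselves (supplier
  capacity is not capped -- the model has no notion of spare
  production).

Export cuts are not allocated pro rata to existing flows but in
*inverse proportion to the partner's GDP*: with `k >= 2` positive
out-edges and `S` the partners' GDP total, partner `j` absorbs the
fraction `((S - GDP_j)/S) / (k - 1)` of the cut (a single partner
absorbs everything).  Poor importers therefore take disproportionate
cuts -- a quantity-only stand-in for the price mechanism by which rich
countries would outbid poor ones in a shortage.

Every country holding a deficit then tries to shed it by cutting its
own exports under the same rule.  All deficit holders act
simultaneously each step, using the weights at the start of the step;
the dynamics themselves impose no ordering among deficit holders, and
synchronous updates make the result independent of country
enumeration order.
Edges truncate at zero; whatever part of a cut was blocked by
truncation stays with the cutter and is retried next step over the
surviving edges, so a partner whose link has emptied absorbs nothing
further.  Deficits are always recomputed from the current flow matrix
against baseline demand, never accumulated incrementally, which
removes drift.  The cascade stops when no country with a deficit above
tolerance still has export flow above tolerance to cut.

Two consequences are worth stating because the test-suite leans on
them.  First, conservation: summing the deficit definition over
countries, the flow terms cancel exactly, so the total deficit equals
the original shock at every step -- calories are only moved, never
created or destroyed.  Second, termination: after the initial import
boost, total export weight is non-increasing, and every active step
strictly reduces it, so the process terminates for any positive
tolerance.

Decisions taken where the dynamics were genuinely open:

* the import channel operates only in the initial compensation of the
  origin; all subsequent shedding is via export cuts;
* the cut rule applies to *all* positive out-edges, including edges
  pointing back toward the origin -- this is what produces the observed
  "echo", part of the shock returning to the spreader (the `twoblock8`
  fixture asserts it);
* an origin with `alpha < 1` but no baseline imports reroutes the
  import share through the export channel (with a warning); whatever
  exceeds its exports stays home as deficit.  This keeps conservation
  exact in a corner the dynamics leave unspecified;
* the convergence tolerance defaults to `1e-6` relative to the shock,
  and the step cap to 10,000; both are exposed.

## The synthetic generator

The real 2013 calorie trade network is built from several proprietary
and semi-structured sources, so the package ships a seeded generator
that emulates its statistical structure instead: 172 countries,
directed density ~0.358, reciprocity ~0.610, a single weakly connected
component, undirected diameter 2-3, heavy-tailed strengths, strongly
negative total-degree disassortativity, and GDP positively
rank-correlated with export strength.

The recipe: a latent log-normal country "size" (sdlog default 1.4)
combined with a log-uniform population; the smallest 15% of countries
are import-only (no out-edges), reproducing the observed pattern of a
giant strongly connected trade core with a fringe of small countries
outside it -- and guaranteeing that origin-to-destination distance can
be infinite, a regime the dyadic regressions distinguish.  Exporter
pairs connect with probability proportional to the sum of their scaled
sizes, with the proportionality constant found by bisection and the
mutual/single/import-only edge budget solved in closed form so the
*expected* density and reciprocity equal their targets; single edges
orient from the larger country with probability 0.8.  Edge weights are allocated from each importer's
import budget -- a uniform 15-45% of its domestic supply -- split across
its suppliers in proportion to exporter size.  Because no country
imports more than 45% of its supply (plus at most one small
connectivity-repair edge), derived production is positive by
construction.  GDP is population times a per-capita term that shares
the latent size, giving the positive GDP/out-strength association.
Size-sum attachment is what produces disassortativity: small countries
connect almost exclusively to hubs, while hubs connect to everyone.

What the generator does *not* emulate: geography and regional blocks,
product composition, the identity of real countries, and the real
network's exact weight scale (its mean link weight is matched only in
order of magnitude).  Passing tests on generated networks therefore
demonstrate correctness of the machinery and reproduction of
qualitative structure, not quantitative claims about the real 2013
network.  Supply per capita is drawn uniformly from 1800-3600
kcal/person/day, spanning observed national averages; population is
log-uniform over 1e5-1e9.

## Experiments and derived statistics

`run_grid()` shocks every country in turn at every `alpha` in
{0, 0.5, 1} (516 cascades, 88,752 dyadic outcomes at the defaults).
From the grid:

* **exposure** -- mean final deficit (kcal/person/day) of a country
  over all origins.  The origin's own simulation is included by
  default (the average is over "all the countries in the network");
  a flag excludes it for sensitivity analysis;
* **hedging** -- 1 minus the fraction of its own shock a country
  retains in its own simulation;
* **reserves** -- the 95th percentile of a country's pooled deficits
  across all origins and alphas, i.e. the buffer stock that covers all
  but the worst 5% of simulated outcomes; reported in kcal/person/day
  and as a percentage of per-capita daily supply, restricted to
  countries above one million population.  The percentile uses linear
  interpolation between order statistics (type 7), fixed for
  bit-reproducibility;
* **vulnerability counts** -- per (country, alpha), how many origins
  leave the country with at least 250 (or 500) kcal/person/day of
  deficit -- 1/8 and 1/4 of a recommended adult intake;
* **rank score** -- within each simulation, destinations are ranked by
  deficit ascending (ties get average ranks, which keeps the total
  rank mass invariant); ranks are summed per country over simulations
  and log-transformed.

## Regressions

Three models link outcomes to network position, all with
heteroskedasticity-robust (HC1-style sandwich) standard errors:

* **Tobit** for the dyadic deficits, which are mostly exact zeros:
  censored-normal maximum likelihood (zeros contribute the mass below
  zero), fitted via `survival::survreg`; McFadden pseudo-R-squared
  against the intercept-only fit.  With nothing censored the estimates
  coincide with least squares -- the suite asserts this to 1e-6;
* **negative binomial (NB2)** for the exceedance counts via
  `MASS::glm.nb`, falling back to Poisson with a warning when the
  dispersion is estimated at the boundary (kappa -> 0);
* **OLS** for the continuous log rank-sum score.

Covariate conventions follow the display scale of the analysis:
clustering and PageRank multiplied by 1,000, betweenness and strengths
entered as `log(1 + x)` (the `+1` handles structural zeros), GDP per
capita in logs, shock size in per-capita daily terms of the
*destination* population and log-transformed by default (`log1p`), with
a switch to levels -- the level-vs-log choice is genuinely ambiguous in
the source analysis and both are supported.  Distance regimes enter as
mutually exclusive indicators: domestic (origin = destination), direct
edge (omitted baseline), indirect (finite directed distance >= 2), and
no directed path.  Alpha enters as dummies; all network covariates are
pre-shock quantities, so they do not vary with alpha.
Per-standard-deviation coefficients for display are slope times
covariate SD, with indicator variables passed through and standard
errors rescaled identically (t statistics unchanged).

## Topology measures

Degrees and strengths count positive-weight edges.  C4 is the share of
a country's four largest suppliers in its imports (0 for an
import-free country, which cannot be reached through the import
channel).  Clustering is the unweighted local coefficient on the
undirected projection; betweenness uses directed unweighted shortest
paths (raw counts, log-transformed only in the regressions); hub
scores are weighted HITS (non-negative, unit 2-norm); PageRank is
weighted with damping 0.85.  ANND/ANNS follow the directional
definition: the mean neighbour degree/strength over the alpha-directed
neighbourhood, with the `tot` neighbourhood the *union* of in- and
out-neighbours while `tot` degree/strength of a node is the in+out
*sum* -- the union/sum convention is stated here prominently because
aggregate conventions differ across the literature.  Assortativity
coefficients are Pearson correlations of own degree (strength) with
ANND (ANNS); regular graphs where either side has zero variance report
NA.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at the reference scale (one
172-country generation, its 516-cascade grid, the 88,752-row dyadic
table) plus several hundred 10-20-country cascades for conservation
and oracle-equivalence sweeps; estimator-recovery simulations use
n = 5,000 (Tobit) and n = 516 (negative binomial), sizes at which
3-standard-error recovery bands are informative without being slow.
The optimized engine is validated against `oracle_cascade()`, a
deliberately naive dense-matrix reimplementation, to an absolute
tolerance of 1e-9 kcal on small-weight test networks.  Determinism is
treated as a feature throughout: country order is sorted id order,
every random routine takes a seed, and report files are byte-identical
across reruns.

## Limitations

The model moves quantities, not prices; demand is perfectly inelastic
at baseline supply; stockpiles do not cushion the cascade itself (they
enter only through the reserve statistic); only one origin is shocked
per run; and all origins are treated as equally likely when averaging.
The synthetic generator reproduces signs and tails, not magnitudes:
coefficients estimated on synthetic grids should be compared to the
real-data analysis qualitatively (signs, orderings), never numerically.
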