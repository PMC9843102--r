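---
title: "Maritime connectivity and the risk of An. stephensi introduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maritime connectivity and the risk of An. stephensi introduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lasimti)
```

## The problem

*Anopheles stephensi* is an urban-adapted, container-breeding malaria vector
whose African detections have clustered in and near seaports. If marine
cargo is the introduction pathway, bilateral shipping data collected for
trade economics can be repurposed as an early-warning instrument: countries
strongly and quickly connected to places with established vector populations
should be surveilled first. This vignette describes the model this package
implements, the choices made where the design was genuinely open, and what
the synthetic test bed does and does not establish about real data.

## From shipping indicators to a connectivity index

The Liner Shipping Bilateral Connectivity Index (LSBCI) of a country pair is
the simple average of five indicators of the liner-shipping service between
them: the minimum number of transshipments, the number of countries with
direct routes to both, the number of common one-transshipment connections,
the number of carriers competing on the route, and the size (TEU) of the
largest ship on the route with the fewest carriers. Each indicator is
min-max normalized **across all pairs in the supplied table** before
averaging, so an LSBCI is only comparable within the table it was computed
from. Two consequences matter in practice:

* *Orientation.* A connectivity index must reward directness, so the
  transshipment count is flipped (`lower_better`) before averaging while the
  other four indicators enter as `higher_better`. Published descriptions of
  the index are silent on this inversion, so `compute_lsbci()` takes the
  orientation map as an argument (`default_orientations()`) rather than
  hard-coding it; analyses of precomputed LSBCI values bypass the question
  entirely.
* *Degenerate columns.* If an indicator is constant across all pairs its
  range is zero; the column is mapped to all zeros and a warning is raised.
  This keeps the output deterministic and bounded instead of propagating
  `NaN`, at the cost of pulling the average down — the warning is the signal
  to inspect the input.

Min-max normalization makes every LSBCI lie in [0, 1] and makes the index
invariant to positive affine rescaling of any raw indicator column (changing
the unit of ship size cannot change the index); both properties are enforced
by the test suite over randomized tables.

## The introduction-risk score

For a target country *t* and a source-population country *s* (a country with
an established *An. stephensi* population), the introduction likelihood is

LASIMTI(t, s) = LSBCI(t, s) / days(t, s),

where days(t, s) is the sailing time between the countries' principal ports
at a uniform vessel speed. Dividing by transit time encodes the biology:
eggs and larvae on board survive short crossings far better than long ones.
Targets are ranked by the LASIMTI sum over all sources.

Real bilateral tables are sparse. A pair absent from either the connectivity
or the transit-time table contributes zero to the sum — the score can only
credit documented connections — and each such omission is logged; a target
with no recorded source pair at all scores zero with a warning rather than
an error, because dropping the country would silently shorten the ranking.
Ties in any ranking break alphabetically by country code so that output
files are reproducible.

## Combining with habitat suitability

Introduction (can it arrive?) and establishment (can it persist?) are
different risks. The package consumes a per-country scalar Habitat
Suitability Index in [0, 1]; how a spatial suitability surface is reduced to
one number per country is deliberately left to the caller. Two combination
rules are implemented because the choice is genuinely open:

* `hsi_then_lasimti` (default): lexicographic — rank by HSI, break ties by
  LASIMTI sum. Chosen as the default because it matches the way combined
  rankings are usually reported for this system.
* `product`: rank by `lasimti_sum * hsi`, a symmetric compromise that lets a
  very strong introduction signal offset moderate suitability.

Under both rules a country with *missing* HSI ranks after every HSI-bearing
country (ordered among the missing by LASIMTI sum). This mirrors how
island nations without suitability estimates drop when combined rankings are
built, and it is the conservative choice: a missing estimate is not evidence
of suitability.

## The trade network and PageRank

The intracontinental network links each country to the partners whose LSBCI
ties into its top *k* = 3 values among eligible partners; exact ties at the
third value are all kept (so out-degree may exceed 3), and zero-LSBCI pairs
are never eligible — an edge with no service carries no risk. Tie detection
uses exact equality of the input values as read, since published index
values tie exactly when they tie at all.

An optional travel-time cutoff (14 days — the period the vector's eggs
survive desiccation in transit) is applied to the eligible set **before**
top-k selection. The alternative — select the top 3 first, then delete
far-away partners — would disconnect a country whose three best partners all
lie beyond the window even when reachable partners exist; pre-filtering
keeps every reachable country connected where possible, which is the right
bias for a surveillance instrument. Pairs not covered by the transit-time
table are ineligible while the cutoff is active, for the same conservative
reason that missing pairs contribute zero to LASIMTI.

Node importance is weighted, directed PageRank: the stationary distribution
of a vessel that, with probability *d* = 0.85, follows an out-edge chosen
proportionally to LSBCI weight and otherwise jumps to a uniformly random
country. 0.85 is the default of the igraph implementation that analyses of
this kind conventionally use; it is configurable. Dangling nodes (no
out-edges — only possible in hand-built or cutoff networks) redistribute
their mass uniformly, preserving the probability-distribution reading of the
result. The implementation is plain power iteration on the weighted
transition matrix with an L1 stopping tolerance of 1e-10 (cap 1000
iterations); the suite verifies it against the dominant eigenvector of the
explicitly assembled dense Google matrix, against analytic identities
(mutual pair → 1/2 each; equal-weight ring → 1/n; a node with no in-edges in
a dangling-free graph → exactly (1 − d)/n), and against igraph as an
independent library cross-check.

## The synthetic test bed

No public deposit of real bilateral LSBCI values, AIS-derived transit times,
or per-country suitability reductions exists, so every pipeline stage is
exercised on synthetic data from `gen_scenario()`:

* **Connectivity**: i.i.d. Beta(2, 6) per unordered pair — right-skewed,
  most pairs weakly connected with a few strong links, qualitatively like
  real liner-shipping tables. Connectivity is generated independently of
  geography because a liner index measures service topology, not distance.
* **Transit times**: each country gets one port placed uniformly at random
  on a sphere of radius 6371 km; days = great-circle distance / (14 knots ×
  1.852 km/h × 24 h). This mirrors the uniform-speed methodology of
  AIS-derived transit times and guarantees symmetric, strictly positive,
  triangle-plausible times (antipodal ports ≈ 32.2 days).
* **HSI**: uniform on [0, 1] with an exact, configurable missing fraction.
* **Planted signal**: one target's connectivity to every source can be
  multiplied by a boost (capped at 1), creating a country that *should* be
  ranked first — the answer key for recovery experiments.

Everything is a pure function of the scenario seed; written scenarios are
byte-identical across calls and satisfy every input-validation rule of the
readers, so the generator doubles as the fixture factory for all tests.

A known limitation of this design is worth stating plainly: with ports
scattered uniformly over the whole sphere, transit times span roughly 1–32
days, so the 1/days factor varies across targets by more than an order of
magnitude. A moderate multiplicative boost to one target's *connectivity*
therefore need not dominate the LASIMTI ranking — a mediocre competitor that
happens to sit close to the sources can outscore it. Planted-signal
recovery under this generator measures the joint effect of connectivity
signal and transit-time noise, not connectivity recovery alone; real
geographies, where candidate targets share a coastline and transit times to
distant sources are far more homogeneous, are considerably more favorable to
the signal than this stress test.

What passing tests show, and do not show: they establish the algebraic
contracts (normalization, bounds, monotonicity, tie handling, conservation
of PageRank mass, byte-level determinism) on data with the right shapes and
laws. They cannot certify agreement with published rankings computed from
proprietary inputs, and they do not model temporal correlation between
years, port-level structure within countries, or reporting gaps that are
correlated with trade volume (real missingness is not random).

## Problem sizes and numerical choices

The test suite exercises PageRank on 100 random digraphs of up to 10 nodes
(oracle agreement to 1e-8, mass conservation to 1e-9), network construction
on 100 random connectivity matrices of up to 12 countries against
brute-force enumeration, index properties on 1000 randomized cases,
recovery experiments on 100 seeded scenarios of 30 targets and 4 sources,
and end-to-end determinism on a 40-country scenario — sizes chosen so the
whole suite runs in well under a minute while every code path, including
ties, dangling nodes, and missing data, is hit. Power iteration starts from
the uniform vector; convergence is declared on L1 change, which is the
natural metric for a probability vector. All ranking tie-breaks are
deterministic (alphabetical), so no output ever depends on input row order.
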