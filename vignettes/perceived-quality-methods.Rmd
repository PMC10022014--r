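---
title: "Measuring perceived quality of healthcare providers from bypass behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring perceived quality of healthcare providers from bypass behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqindex)
```

## The problem

In dense informal settlements, a person seeking outpatient care can usually
choose among many healthcare providers (HCPs) within walking distance: small
private clinics, public clinics, and private and public hospitals. When
someone walks past a cheap, nearby clinic to queue at a more distant, more
expensive hospital, that *bypass* reveals something the provider's price and
location cannot: the person believed the visited provider offered better
care. `pqindex` turns a table of observed visits into a per-facility
**Perceived Quality Index (PQI)** by aggregating these revealed-preference
signals, controlling for every cost component we can measure.

## The model

### Generalized access cost

For an individual at dwelling $d$ considering facility $f$, the generalized
access cost collapses money and time into one currency figure:

$$
AC(d, f) \;=\; c_{\text{transport}} + c_{\text{treatment}}
\;+\; v \,\big( t_{\text{travel}}(d,f) + w \, t_{\text{wait}}(f) \big)
$$

where $v$ is the value of time (currency per minute) and $w$ a relative
weight on waiting time (default 1, i.e. one common rate). Travel time is the
shortest path over the road-and-footpath network divided by a constant
walking speed; the model assumes all trips are made on foot and start at
home. This is the standard additive linear generalized cost of the
accessibility literature; we deliberately use no nonlinear time weighting.

Costing is asymmetric by design. For the facility a record actually visited
we use the *record's own* consultation cost, waiting time and transport
cost — the costs that person really faced. For every alternative facility we
use the facility's mean price and mean waiting time with zero transport cost
(the on-foot assumption). `means_everywhere = TRUE` switches the visited
facility to means too, as a sensitivity mode; in our simulations it changes
results only marginally.

### Bypass events and the PQI

A visit to facility $f^*$ bypasses facility $f$ when
$AC(d, f) < AC(d, f^*)$ — *strictly* lower; exact ties are not bypasses.
Each event carries the weight $\Delta = AC(d,f^*) - AC(d,f) > 0$. Starting
from 0 for every facility, each event adds $+\Delta$ to the visited
facility's PQI and $-\Delta$ to the bypassed facility's, so the index is
exactly zero-sum over facilities. A facility that could easily have been
visited (much cheaper) and was passed over is penalised more than one that
was nearly as expensive as the chosen provider.

Only *substitutable* providers — those offering general outpatient
('polyclinic') care — enter the candidate set. A dentist bypassed on the way
to a maternity clinic says nothing about perceived quality, so such
facilities carry `substitutable = FALSE` and never appear in any profile,
event or PQI row.

### What the PQI is and is not

The PQI is a residual: whatever offsets a measured cost disadvantage. It
captures reputation, familiarity and customer service as much as technical
quality, and it is **not** a neutral estimator of a latent quality scale.
Two structural biases matter when interpreting it:

* A facility with a low access cost is *mechanically* penalised: it is
  below the cost of many visited alternatives and therefore accumulates
  negative contributions roughly in proportion to how often it is anyone's
  cheaper option. Cheap public clinics therefore sit below pricier private
  clinics even at equal latent quality.
* The positive term scales with the cost premium people paid, not with
  quality directly; a facility's index mixes its quality signal with the
  geometry of who lives near it.

These biases are inherent to the construction, and they drive several of
the design choices below.

## Data cleaning and imputation conventions

* Records whose time fields carry an enumerator placeholder (default set
  `{999}` minutes) are dropped, as are negative costs/times and travel
  times above a plausibility cap (default 720 min — 12 h on foot; the cap
  is configurable because no canonical bound exists).
* Every dropped record is attributed to exactly one rule in the cleaning
  report, and cleaning is idempotent.
* A recorded **zero is a valid observation**, never treated as missing.
* Missing consultation costs and waiting times are imputed with the mean of
  the non-missing observed values *at the same facility*; a facility with
  no observations falls back to its four-way class mean, then to the global
  mean. The facility-mean step is the substantive rule; the fallback chain
  is this package's choice for small samples. Non-missing values are never
  modified, and every imputation is logged.
* Missing transport cost on a visited record is costed as 0, consistent
  with the on-foot assumption.

## Routing choices

* Sites snap to the nearest network *node* by straight-line distance (ties
  broken by lowest node id). Edge-interior snapping would be marginally more
  accurate but the difference is negligible on dense footpath networks; we
  document node snapping as an approximation.
* Walking speed defaults to 80 m/min (4.8 km/h), configurable.
* OSM-derived extracts often contain stray disconnected fragments.
  `connect_components()` bridges each smaller component to the closest node
  of the largest one with a straight-line edge at a 1.5× length penalty —
  a stand-in for informal, unmapped paths — rather than failing or silently
  dropping sites.
* The travel-time matrix is built from single-source shortest-path trees
  per facility, which is numerically identical to pairwise queries.

## The synthetic settlement generator

Real visit surveys of this kind are rarely shareable, so the package ships
a generator that emulates their structure end to end and plants a known
latent quality, making the whole pipeline testable against ground truth.

What it emulates: a square settlement with a dense footpath network (random
geometric graph plus its Euclidean minimum spanning tree, so it is always
connected); dwellings and clinics scattered uniformly; hospitals drawn with
probability proportional to distance from the centroid so they are sparser
and farther — mean travel time to hospitals exceeds that to clinics, the
geometry observed in real settlements; per-facility consultation prices and
waiting times jittered around class means (hospitals dearer, public
facilities slower); visits drawn from a multinomial-logit rule
$P(f) \propto \exp\{\beta\,(q_f - AC(d,f))\}$; reported travel times =
true times × lognormal noise (sdlog 0.2); a fraction of cost/wait fields
blanked and a fraction of travel times replaced by the 999 placeholder.

What it does not emulate: symptom severity and condition mix, trips that
start away from home, public-transport legs, household covariates,
enumerator effects beyond the simple placeholder, and spatial correlation
of wealth. Passing tests therefore show the pipeline implements the method
faithfully under its own assumptions — not that those assumptions hold in
any particular real settlement.

### Default scenario and calibration

| parameter | default | rationale |
|---|---|---|
| area | 2 km × 2 km, 400 nodes | compact settlement; everything walkable |
| sites | 500 dwellings; 20/16/8/6 facilities (priv. clinic / pub. clinic / priv. hosp. / pub. hosp.) | clinics numerous, hospitals sparse |
| walking speed | 80 m/min | typical adult pace |
| value of time | 1 currency/min | unit rate; must be set for real data |
| prices (class means) | 80 / 30 / 300 / 120 | private dearer than public; hospitals dearer than clinics |
| waits (class means, min) | 15 / 40 / 30 / 90 | public slower than private |
| quality means $q$ | 50 / 0 / 250 / 400 | see below |
| quality spread | sd 50 | equal to the smallest between-class gap |
| choice sensitivity $\beta$ | 0.01 /currency | see below |
| reporting noise | lognormal sdlog 0.2 | keeps reported≈computed times strongly correlated |
| missing / placeholder rates | 5% / 2% | light survey messiness |

$\beta$ was calibrated once on choice-share diagnostics: at 0.01 the logit
spread over a typical cost range (~100–450 currency) makes choices clearly
cost-sensitive without collapsing to pure cost-minimisation, and planted
quality remains recoverable; larger values wash out the quality signal,
smaller ones the cost signal.

The planted class means deserve a note. Because the index mechanically
penalises cheaper facilities (first bias above), a planted ordering that
puts the *cheaper* clinic class on top is structurally unrecoverable: the
index will always rank dear private clinics above cheap public ones at
equal quality. The generator therefore plants quality in the ordering the
index can surface — public hospitals highest, hospitals above clinics,
private clinics slightly above public clinics — which is also the class
ordering reported in field studies of settlement healthcare choice. The
within-class spread (sd 50) is set at the smallest between-class gap so the
class structure dominates without making facilities interchangeable.

## Numerical choices

* Strict inequality defines a bypass; tie totals produce no event.
* Event weights are raw currency differences, un-normalised — the simplest
  reading of weighting "by the magnitude of the difference". A per-visit
  normalised variant (each visit's weights divided by its event count) is
  available for sensitivity analysis.
* Zero-sum conservation is exact up to floating-point accumulation; tests
  assert a relative residual below 1e-9 (and exactness on integer-cost
  fixtures).
* The logit simulation subtracts the row maximum before exponentiating, so
  steep sensitivities (e.g. $\beta = 50$ in the null model) do not overflow.
* All generator randomness derives from the scenario seed (sub-seeds:
  network = seed, sites = seed+1, visits = seed+2), so identical scenarios
  reproduce byte-identical outputs.
* Degenerate inputs: an empty visit table flows through to an all-zero PQI;
  correlations with fewer than 3 pairs or zero variance are reported as
  undefined with a warning rather than silently dropped.

## Validation design

The test suite validates each stage against an independent oracle: routing
against brute-force enumeration of simple paths on small random graphs,
bypass detection against exhaustive pairwise comparison, aggregation
against explicit tallies, imputation against hand-computed means, and the
end-to-end pipeline against the generator's planted truth. Two end-to-end
properties summarise the method:

* **Null model** — with flat quality and steep cost sensitivity, simulated
  patients choose their cost-minimal facility ≥99% of the time, and those
  cost-minimal visits generate zero bypass events and an all-zero PQI.
* **Recovery** — on the default scenario (50 facilities, 500 dwellings,
  2,000 visits, 5 seeds) the Spearman rank correlation between PQI and
  planted quality averages ≈0.75–0.8; in ≥90% of seeds every hospital
  class outranks every clinic class on mean PQI.

Problem sizes in the routine tests (60-node networks, a few hundred visits
for unit tests; the full default scenario for the end-to-end properties)
were chosen to exercise every code path with comfortable statistical margins.

## Limitations

Beyond the generator's non-goals listed above: the index inherits the
method's identification limits — it cannot distinguish perceived from
technical quality, it is biased against cheap facilities by construction,
and within a facility class its ranking is noisy at realistic visit counts
(a few dozen visits per facility). Reported correlations are descriptive
Pearson coefficients, not causal estimates.
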