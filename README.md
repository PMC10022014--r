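# pqindex

Quantifying the *perceived quality* of healthcare providers in informal
settlements from revealed-preference visit data.

## The problem

People in dense urban settlements can usually reach many healthcare
providers (HCPs) on foot — private and public clinics and hospitals. They
often do **not** choose the nearest or cheapest one. When a patient walks
past a cheaper, closer provider to visit a dearer, farther one, that
*bypass* reveals a willingness to pay — in money, travel and waiting time —
for something unmeasured: perceived quality. `pqindex` is for health-services
researchers who have (or want to simulate) geotagged dwellings and
facilities, a road-and-footpath network, and individual visit records, and
who want to turn observed bypasses into a per-facility quality score.

## The method

For a visit from dwelling $d$, every substitutable facility $f$ gets a
generalized access cost in currency units

$$AC(d,f) = c_{\text{transport}} + c_{\text{treatment}} + v\,(t_{\text{travel}} + t_{\text{wait}}),$$

with $t_{\text{travel}}$ the shortest network path walked at constant speed
and $v$ the value of time. The visited facility is costed from the record's
own reported values (after facility-mean imputation); alternatives are
costed from facility means with zero transport cost (on-foot assumption).
A **bypass event** is any alternative with strictly lower $AC$ than the
visited facility, weighted by the difference. The **Perceived Quality
Index (PQI)** starts at 0 for every facility and accumulates $+\Delta$ for
the visited and $-\Delta$ for the bypassed facility per event — a zero-sum,
cost-controlled residual in which a high score means patients repeatedly
paid a premium to get there.

The package covers the whole pipeline: loading and validating
GraphML/GeoJSON/CSV inputs, cleaning (999-minute placeholders, implausible
values; zeros are valid observations), facility-mean imputation, pedestrian
routing, access-cost profiles, bypass detection, PQI aggregation, and
class-level reporting (popularity, travel time and access cost by class,
Pearson correlations, home-origin validation, mode shares). A synthetic
settlement generator with planted latent quality makes every stage testable
without survey data.

## Worked example

```r
library(pqindex)

sc  <- slum_scenario(seed = 42)            # 2 km slum, 50 facilities, 500 dwellings
sim <- simulate_scenario(sc, n_visits = 2000)
a   <- analyze_visits(sim$network, sim$dwellings, sim$facilities, sim$visits)
print(a)
```

```
Perceived-quality analysis
  visits analysed: 1967 (65766 bypass events)
  class summary:
             class n_facilities total_visits mean_visits mean_travel_min
1   private clinic           20          389       19.45           16.29
2    public clinic           16          229       14.31           15.78
3 private hospital            8          158       19.75           17.08
4  public hospital            6         1191      198.50           16.92
  mean_access_cost mean_pqi sd_pqi mean_times_bypassed mean_bypasses_per_visit
1           113.21  -199649  35677              1594.1                   22.93
2            89.39  -249215  29459              1790.4                   13.30
3           357.96   157638  88120               207.6                   42.74
4           260.94  1119886 493030               596.2                   39.50
  visits ~ access cost: r = 0.2766335
  PQI ~ access cost:    r = 0.5755907
  home-origin check:    r = 0.8992 (n = 1967)
```

Reading the output: 33 of 2,000 simulated records were dropped by cleaning
(placeholders, implausible values). Public hospitals — planted with the
highest latent quality — receive by far the most visits per facility
(198.5) and the highest mean PQI (+1,119,886 currency-weighted bypass
units) despite above-average access costs, while cheap clinics accumulate
negative PQI because they are everyone's bypassed cheaper option. The
home-origin check correlates reported with network-computed travel times
(r = 0.90 under the generator's 0.2-sdlog reporting noise). Against the
generator's planted quality this run recovers a Spearman rank correlation
of 0.83:

```r
m <- merge(a$pqi, sim$truth, by = "facility_id")
cor(m$pqi, m$q, method = "spearman")
#> [1] 0.8331733
```

A command-line wrapper over the same functions ships at
`system.file("cli", "pqi.R", package = "pqindex")` with subcommands
`simulate | analyze | report` driven by flat key=value config files.

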