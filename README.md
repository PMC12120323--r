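# baymates

Multi-species passive acoustic telemetry analytics for coastal embayments:
residency, seasonality, space use and social co-occurrence, in one
tidyverse-native R package.

## The problem

Arrays of moored acoustic receivers record time-stamped detections of tagged
fish and sharks for years at a time. Turning those raw `(time, tag, receiver)`
triples into ecology requires a chain of well-defined statistics:

- **Detection indices.** For each individual, the number of distinct
  detection days divided by the days monitored. Two denominators are useful:
  the full monitoring window (`DI_total`, from tagging to the earliest of
  study end, recapture, battery expiry or last detection outside the bay)
  and the days at liberty up to the last in-bay detection (`DI_bay`). The
  same numerator over nested denominators forces `DI_total <= DI_bay`.
  Groups are compared with Kruskal–Wallis / Dunn (Benjamini–Hochberg) or
  Mann–Whitney tests.
- **Seasonality.** Monthly detection-day counts are modelled as
  overdispersed Poisson with a log link, a `log(days in month)` offset,
  species intercepts, a periodic cubic spline over month per species, and
  ridge-penalized individual intercepts — a penalized-IRLS approximation to
  the classical GAMM `count ~ species + s(month, bs = "cc", by = species) +
  s(individual, bs = "re") + offset(log(days))` with quasi-Poisson
  dispersion.
- **Movement networks.** Receivers are nodes; consecutive detections of an
  individual at two receivers within 24 h add an undirected weighted edge.
  Node density (`|visited| / |array|`) and edge density
  (`|edges| / C(|array|, 2)`) summarize the extent of space use, and a
  from-scratch PERMANOVA (Euclidean distances on per-receiver
  detection-proportion profiles, sequential sums of squares, pseudo-F, free
  permutation of observations) tests spatial segregation by species, life
  stage and tagging region.
- **Co-occurrence social networks.** Under the gambit of the group,
  individuals detected at the same receiver within the same clock-aligned
  hour bin are associated. Dyads are weighted by the simple-ratio index
  `SRI = x / (x + y_AB + y_A + y_B)`, and trait assortment is measured by
  the weighted categorical assortativity
  `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` with significance
  from a node-permutation null (trait labels shuffled over nodes, edges
  fixed).

Because real receiver downloads are rarely shareable, the package ships a
fully ground-truthed synthetic detection generator (`sim_scenario()`,
`simulate_detections()`) that emulates a ~59-receiver bay array, four
species across life stages, cosine seasonal peaks, region-biased receiver
use and a tunable excess of conspecific co-detection — so every statistic
above can be validated end to end against known truth.

## Worked example

```r
library(baymates)
library(dplyr)

sim <- simulate_detections(sim_scenario(seed = 42))
ds  <- filter_dataset(sim$detections, sim$tags, sim$receivers)
ds
#> <bay_dataset> 229563 detections | 128 individuals | 59 marine receivers
#>   excluded: 4 individuals (below_min_days: 4); min_days = 10, tz = Etc/GMT-2

detection_indices(ds) |>
  group_by(species) |>
  summarise(n = n(), mean_di_total = mean(di_total), mean_di_bay = mean(di_bay))
#>   species          n mean_di_total mean_di_bay
#> 1 A_japonicus     21         0.157       0.160
#> 2 C_carcharias    46         0.414       0.416
#> 3 C_taurus        38         0.210       0.212
#> 4 L_amia          23         0.179       0.181

di <- detection_indices(ds)
compare_groups(di$di_total, di$species)
#> Kruskal-Wallis chi-squared = 107.2, df = 3, p = 4.294e-23
#> Dunn post hoc (BH-adjusted): ...

net <- cooccurrence_network(ds, period = as.Date(c("2014-10-01", "2015-09-30")))
node_permutation_test(net, net$traits$species, n_perm = 1000, seed = 1)
#> Assortativity r = 0.901, node-permutation p = 0.000999 (1000 permutations, greater)
```

The filter keeps marine detections inside each animal's monitoring window
and drops individuals seen on fewer than 10 distinct days. The mean
detection indices echo the generator's per-species daily presence rates;
the Kruskal–Wallis test flags between-species differences in residency and
Dunn's test locates them; the assortativity test shows individuals
co-occurring with conspecifics far more than a label-shuffled null allows
(the generator's co-assignment mechanism at work).

Other entry points: `monthly_detection_table()` + `fit_seasonal_model()` +
`autoplot()` for seasonal curves, `movement_networks()` /
`network_densities()` / `aggregate_networks()` for space use,
`receiver_use_profiles()` + `permanova()` for segregation, and
`plot_daily_detections()` for the classic barcode plot. Fitted objects have
broom-style `tidy()` / `glance()` methods.

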