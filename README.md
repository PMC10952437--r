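# flocknet

Local population size and foraging social-network structure from RFID
visit streams.

Wintering songbirds (the motivating system is the great tit, *Parus
major*) forage in loose fission–fusion flocks at feeders. When a grid of
RFID-equipped feeders logs every landing of a PIT-tagged bird over
repeated weekend samples, the visit streams support a complete analysis of
how **local population size** — the number of distinct individuals at one
feeder in one week — arises from the habitat and shapes social structure.
`flocknet` implements that analysis end to end, for field data of this
schema or for its own synthetic generator:

* **Event detection** — partition each day's visit stream into
  non-overlapping flocking (gathering) events with an overcomplete 1-D
  Gaussian mixture (deterministic, no fixed time window), or a transparent
  gap rule.
* **Association networks** — group-by-individual matrices and undirected
  networks weighted by the simple ratio index,
  SRI = x / (x + y_i + y_j), per location and week.
* **Global metrics** — binary edge density, global clustering
  (3 × triangles / connected triples), mean non-zero edge weight, and
  modularity Q of the best Girvan–Newman (edge-betweenness) dendrogram
  cut, with the connectivity and ≥2-edge usability classifications.
* **Reference models** — a "simple" model (resample N individuals' visit
  sequences from random location-weeks onto a virtual weekend: population
  size without any social factor) and a "social foraging" model
  (checkerboard swaps of the GBI: flock sizes and visit schedules kept,
  partner identities destroyed), each re-analysed exactly like observed
  data and summarized as metric-versus-N curves.
* **Repeatability** — latent-scale repeatability of weekly population size
  from a Poisson GLMM (location random effect + observation-level
  overdispersion), with a one-tailed permutation test that shuffles
  location identities within each year-week.
* **Habitat** — zero-nugget spherical variogram fitted by weighted least
  squares, ordinary kriging of shrub-cover quadrats onto a 10 m grid,
  mean density within 30 m / 100 m of each feeder, distance to the site
  edge, and a zero-truncated negative-binomial GLMM of population size on
  the standardized covariates.
* **Observed-data models** — the transformation/filter conventions
  (square/log transforms, fully-connected and ≥2-edge exclusions, the
  0.0001 modularity split) and the six (G)LMMs linking log population
  size to network structure.
* **Synthetic data** — a generator with known ground truth (latent
  repeatability, event assignments, bonded social units, habitat surface)
  emulating 65 feeders × 13 weekends × 3 winters.

## A worked example

```r
library(flocknet)

cfg <- sim_config(n_locations = 12, n_years = 1, weeks_per_year = 3,
                  location_effect_sd = 0.6, edge_effect = 0,
                  mean_log_popsize = log(12), seed = 424)
sim <- simulate_dataset(cfg)
an  <- analyze_visit_log(sim$visit_log, method = "gmm")

head(an$metrics[, c("location_id", "week", "population_size",
                    "edge_density", "mean_edge_weight", "modularity_q")])
#>   location_id week population_size edge_density mean_edge_weight modularity_q
#> 1         L01    1              11    0.9090909        0.1548495   0.02666009
#> 2         L02    1              16    0.9833333        0.2753194   0.00000000
#> 3         L03    1              16    1.0000000        0.3039451   0.00000000
#> 4         L04    1               5    1.0000000        0.9000000   0.00000000
#> 5         L05    1               8    0.7142857        0.2470867   0.04104232
#> 6         L06    1              26    0.9630769        0.1662565   0.01512040
```

Small populations form single, fully connected flocks with strong
associations; larger ones are sparser with weaker mean edge weight, and
fragmentation (positive modularity) appears at intermediate sizes. The
repeatability of weekly population size, with its permutation null:

```r
rpt <- permutation_test(popsize_table(sim$visit_log), n_perm = 99, seed = 1)
rpt
#> Repeatability of local population size (latent scale)
#>   R = 0.817  (excluding OLRE variance: 0.824)
#>   variance components: location 0.2794, OLRE 0.0031, distribution 0.0596
#>   permutation p (one-tailed, 99 permutations) = 0.01
```

(12 locations over 3 weeks at a configured latent repeatability of 0.84:
the estimate is 0.82 and no permuted dataset reaches it, so p takes its
smallest attainable value, 1/100.) Reference-model curves for the same
data show the simple model sparsest and the swap null densest at matched
population size, with the observed data in between:

```r
curves <- build_null_curves(an, n_replicates = 5, bin_width = 5, seed = 2)
subset(curves, metric == "edge_density" & n_bin == 12.5)
#>            model n_bin       metric      mean         se  n
#>         observed  12.5 edge_density 0.9168137 0.02851074 12
#>           simple  12.5 edge_density 0.8579593 0.01150535 60
#>  social_foraging  12.5 edge_density 0.9407665 0.01027445 60
```

The full pipeline — synthetic data (or a visit-log CSV), events, networks,
metrics, null curves, repeatability, habitat surface, and all model fits,
with every stage written as plain-text files plus a JSON manifest — runs
from one configuration:

```r
run_pipeline(list(seed = 7, out_dir = "out",
                  synthetic = list(n_locations = 12, n_years = 1,
                                   weeks_per_year = 3)))
```

or from the command line via the thin wrapper
`inst/scripts/flocknet run-all --config config.yaml`.

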