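# packsocial

Social-system analysis of coded camera-trap observations of a small animal
group. The package was built for studies of territorial canids — a golden
jackal pack watched by a fixed camera grid — where every 30-second
recording is coded against a 13-behaviour ethogram and the questions are:

1. **Reliability** — can the coder's identifications be trusted
   (Cohen's κ on a re-identification round), and are recordings temporally
   independent (autocorrelation of daily detection counts)?
2. **Dominance** — who outranks whom? Aggression, submission and
   scent-marking events are turned into a win-count matrix
   (aggressor wins; the recipient of a submissive display wins; a scent
   marker wins over every other adult present in the group that day), from
   which **normalised David's scores** give each adult a rank score:

   NormDS<sub>i</sub> = (DS<sub>i</sub> + N(N−1)/2) / N,  with
   DS = w + w2 − l − l2 built from dyadic win proportions
   P<sub>ij</sub> = s<sub>ij</sub>/(s<sub>ij</sub>+s<sub>ji</sub>).

3. **Social structure** — who associates with whom? Co-detection in the
   same recording defines a weighted network (raw counts or the
   simple-ratio index x/(n<sub>i</sub>+n<sub>j</sub>−x)); **eigenvector
   centrality** (power iteration, top node scaled to 1) measures
   direct-plus-indirect influence, and **fast-greedy modularity
   agglomeration** finds communities, with Q > 0.3 flagged as strong
   structure.

A synthetic event-log generator with a known latent hierarchy, planted
association clusters, a dispersal event, a pup cohort and identification
noise makes every stage testable by parameter recovery; see the methods
vignette (`vignettes/packsocial-methods.Rmd`) for the models and the
design decisions.

## Worked example

```r
library(packsocial)

cfg <- synth_config(seed = 7)        # study-like defaults: 7 adults,
sim <- simulate_event_log(cfg)       # dominant pair, dispersal, 6 pups
sim$log
#> <observation_log> 13 individuals (7 adults), 865 events in 865 recordings
#>   2023-01-01 to 2023-04-30

hier <- sim$log |>
  build_dominance_matrix() |>
  davids_scores() |>
  rank_hierarchy()
dplyr::select(hier, id, rank, norm_ds, total_wins, total_losses)
#> # A tibble: 7 × 5
#>   id     rank norm_ds total_wins total_losses
#>   <chr> <int>   <dbl>      <dbl>        <dbl>
#> 1 J02       1    5.10        243           61
#> 2 J01       2    5.07        218           62
#> 3 J06       3    2.77         42          130
#> 4 J05       4    2.34         37           81
#> 5 J03       5    2.04         25           71
#> 6 J04       6    1.97         19           74
#> 7 J07       7    1.72         21          126
```

The two planted dominants (latent strengths 2.5 and 2.3 against 0.6 for
the subordinates) come out on top with NormDS ≈ 5.1 against ≈ 2 for the
homogeneous rest — the shape of a despotic pair over equal subordinates.
NormDS always sums to N(N−1)/2 (= 21 here).

```r
net <- sim$log |>
  restrict_log("2023-01-01", "2023-03-01") |>
  cooccurrence_counts() |>
  association_matrix()          # weight_kind = "count" by default

eigenvector_centrality(net)      # top node = 1 by convention
fg <- fast_greedy_partition(net)
fg
#> <community_partition> 2 communities, Q = 0.00880202 (weak structure)

ct <- simulate_reidentification(sim$log, q = 0.9, seed = 8)
cohens_kappa(ct)
#> Cohen's kappa = 0.8527  (p_o = 0.8667, p_e = 0.0951, n = 120, 13 labels)
```

Q ≈ 0.009 is far below the 0.3 threshold: everyone associates with
everyone in a group this small, so the two detected clusters are only
weakly supported — the expected result for a cohesive pack. An
identification accuracy of 0.9 yields κ ≈ 0.85, "almost perfect"
agreement on the usual scale.

`run_pipeline(analysis_config(...))` chains all of the above over named
date periods (e.g. before/after a dispersal-and-births group change, with
all pups collapsed onto one `"Pups"` node) and writes the hierarchy table,
per-period centrality tables with a modularity footer, partitions, GraphML
and edge-list exports, a JSON summary and a run log. `autoplot()` methods
draw the hierarchy bar chart, the ACF stem plot and the sociogram;
`tidy()`/`glance()` give broom-style summaries.

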