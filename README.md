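# duindex

Usage indicators for primary biodiversity data.

Publishers of species-occurrence datasets get little of the recognition
that citations give authors of papers: datasets are searched and
downloaded, not cited. `duindex` computes a Data Usage Index (DUI) — a
family of scientometric-style indicators built from two ingredients a data
portal already has: an **inventory** of stored records per dataset and a
**usage-event log** (searches, views, downloads per visitor key). It is
aimed at portal operators, node managers and informatics researchers who
want publisher- or country-level usage reports without any citation data.

## The indicators

For an analysis unit *u* (a dataset, publisher, country, region, species
slice, or the world) over a bounded window, the absolute counts are the
searched records *s(u)*, downloaded records *d(u)*, stored records *r(u)*,
search events *S(u)*, download events *D(u)* and dataset number *N(u)*.
From these:

| indicator | formula | meaning |
|---|---|---|
| search density | *s/S* | records retrieved per search event |
| download density | *d/D* | records per download event |
| usage impact (UIF) | *d/r* | downloads per stored record |
| interest impact (IIF) | *s/r* | searches per stored record |
| usage ratio | *d/s* | searched records that were downloaded |
| usage balance | *D/S* | search events leading to a download |
| usage / interest score | *100·U/r*, *100·I/r* | % of records touched at least once |

Relative indices divide a unit's UIF by a ratio-of-sums baseline UIF
(`relative_index()`), and the species-profile-weighted **Usage Crown
Indicator** compares observed downloads with the downloads expected given
the unit's species mix, `UCI = d(u) / Σₚ r_s·U_s`, where *U_s* is the global
per-species expected UIF (`usage_crown_indicator()`); UCI = 1 means usage
on par with the baseline. Supporting machinery: bounce filtering, session
reconstruction with the 30-minute inactivity rule, publisher size classes,
the brute-force size adjustment, rank distributions with Gini/top-k
long-tail summaries, and a seeded synthetic generator
(`simulate_usage()`) that emits inventories, event streams and the exact
injected per-unit counts for oracle testing.

## Worked example

```r
library(duindex)

# Raw counts for a large marine publisher over one month
counts <- data.frame(s = 2092927, d = 555835, S = 42860, D = 601)
ind <- compute_indicator_set(counts, r = 11140298, N = 180)
display_indicators(ind)[, c("search_density", "download_density",
                            "usage_impact", "usage_ratio", "usage_balance")]
#> # A tibble: 1 × 5
#>   search_density download_density usage_impact usage_ratio usage_balance
#>            <dbl>            <dbl>        <dbl>       <dbl>         <dbl>
#> 1           48.8             925.         0.05        0.27         0.014
```

Each search event retrieved ~49 records and each download event ~925; only
5% of the stored records' worth of downloads accumulated in the month
(UIF 0.05), 27% of searched records were downloaded, and 1.4% of search
events led to a download.

```r
# A small herbarium publisher against its national baseline
relative_index(d = 717102, r = 259077,
               baseline = list(d = 1571863, r = 4836771), mode = "rounded")
#> [1] 8.65625   # printed as 8.66: 2.77 / 0.32
```

The publisher's usage impact is ~8.7 times the national ratio-of-sums
baseline. A full synthetic pipeline:

```r
sim <- simulate_usage(sim_config(seed = 1))
filt <- filter_bounces(sim$events)
w <- analysis_window("2009-07-01", "2010-01-01")
annual_report(filt$events, sim$registry, w)   # ranked publisher table
```

A thin command-line front end with `simulate`, `compute`, `report` and
`rank` verbs lives at `inst/cli/dui.R`.

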