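---
title: "The Data Usage Index: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Data Usage Index: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duindex)
```

## Why usage indicators

Primary biodiversity data — species-occurrence records published as
datasets through aggregating portals — are used heavily but cited rarely,
because no robust dataset-citation mechanism exists. The Data Usage Index
treats the dataset record as the analogue of a journal article and the
dataset as the analogue of a journal, and measures *interest* (searching
and viewing of records) and *usage* (downloading of records) from the
portal's own event logs. Indicators attach to whatever aggregation "unit"
the analyst defines: a dataset, a publisher, a country or region, a species
slice, or the world.

## The counting model

Every computation starts from two tables.

The **inventory** fixes the denominators: stored records per dataset
(`total_records`), optionally broken down per species, optionally with
individual record identifiers. The stored-record number $r(u)$ of a unit is
the sum over its member datasets; when record identifiers are available for
all members, records shared between datasets are counted once (national
totals can genuinely be smaller than the sum of the national publishers'
holdings). Without identifiers there is no defensible duplicate-detection
rule, so `record_number()` returns the plain sum and flags the result
`dedup_unavailable` rather than guessing.

The **event log** carries one row per visitor action: a timestamp, an
opaque anonymized IP key, an event type, the target dataset and the number
of records touched. Types `search` and `view` are interest events; types
`download` and `taxonomy_download` are usage events (taxonomy downloads
are record downloads in every respect that matters to $d$ and $D$, so they
count there); `metadata_view` touches no records. Before any indicator is
computed, **bounces** are removed: all metadata views plus any
search/view touching zero records. Observed portal bounce rates are around
two thirds; the removed fraction is reported once and then plays no
further role.

From the filtered log, `count_events()` produces the per-unit raw counts
$s, d, S, D$ plus $U$ and $I$ (distinct downloaded/searched record
identifiers — computable only when events carry ids) and $n$, the member
datasets actually used. The fourteen indicators in
`compute_indicator_set()` are ratios of these with $r$ and $N$; the
algebraic identity $(d/s)(s/r) = d/r$ ties the usage ratio, interest
impact and usage impact together and is asserted in the tests.

### Conventions worth stating

* **Windows are half-open**, $[\mathrm{start}, \mathrm{end})$. Published
  accounts of usage windows never state edge handling; half-open intervals
  make adjacent windows partition time, so raw counts are exactly additive
  over a partition — a property the tests assert.
* **Sessions split at a gap of at least 30 minutes.** The rule defines a
  returning ("loyal") visit as the same IP key reappearing after an
  interruption of at least 30 minutes, so a gap of exactly 30 minutes
  starts a new session; the first session of a key is a unique visit.
  The IP key is treated as fully opaque — no prefix coarsening, no
  institutional resolution.
* **Stable denominators.** $r(u)$ is read from the inventory snapshot
  under the window's `record_count_convention` (default `end_of_window`,
  i.e. the snapshot is taken to describe holdings at the close of the
  window). With one snapshot all conventions coincide; the convention is
  carried in output manifests so multi-snapshot extensions stay explicit.
* **Zero denominators yield `NA`** (undefined), never 0 or infinity:
  a unit with no search events has no search density, rather than an
  infinite or zero one.
* **Display rounding is half-up to two decimals** (three for the usage
  balance, whose typical magnitude is a few thousandths), with a
  `sqrt(eps)` guard against binary representation of exact ties; internal
  values are always full precision. The usage balance is reported as a
  plain ratio by default (with a percent option), matching how worked
  usage tables print it.

## Relative indices and the crown indicator

Absolute impact factors are only informative against a fixed point.
`relative_index()` divides a unit's UIF ($d/r$) by a **ratio-of-sums**
baseline: $\mathrm{UIF}_{\mathrm{base}} = \sum_i d_i / \sum_i r_i$ over the
$n$ baseline units. Summing before dividing weights large holdings more
than averaging per-unit ratios would; it also gives the consistency
property (asserted on synthetic data) that the $r$-weighted mean of member
indices is exactly 1. The baseline includes the unit itself by default —
the world contains the unit — and substituting $s$ for $d$ yields the
interest-impact (IIF) index.

Two arithmetic modes exist because published tables are computed from
*printed, two-decimal* impact factors: in `rounded` mode each UIF is
rounded half-up to two decimals before division (6.50/0.32 = 20.31), while
the default `full` mode keeps full precision (19.99 for the same pair).
The package treats full precision as the honest default and the rounded
mode as a reproduction device.

Publisher profiles differ: some species are intrinsically more
download-dense than others, just as some research fields are more
citation-dense. The **Usage Crown Indicator** normalizes for that. Each
unit has a species profile $\{(r_s, d_s)\}$; the global expectation for a
species is $U_s = \sum_u d_s^{(u)} / \sum_u r_s^{(u)}$ (ratio of sums
again), and

$$\mathrm{UCI}(u) = \frac{d(u)}{\sum_{s=1}^{p} r_s \, U_s},$$

observed downloads over the downloads expected if every species in the
unit's profile were used at the global rate. UCI = 1 means usage on par
with the baseline given the unit's species mix. Only the prose constraints
of the original description survive (its display equations are not
available in the source text we reconstruct from); the ratio-of-sums form
above is the one consistent with those constraints and with the
crown-indicator literature the description invokes, and the package
implements it as such. Three identities pin the implementation down and
are tested: the union of the reference units scores exactly 1; a
single-species unit reduces to $\mathrm{UIF}(u)/U_s$; and uniformly
scaling all downloads leaves the UCI fixed.

Species in a profile but absent from the baseline are an **error**, not a
skip: silently dropping them would change $p$ and bias the expectation
downward. Species with zero stored records across the reference set are
omitted from the baseline with a warning — no expectation is defined for
them.

Event logs record the target *dataset* of a download, not the species of
each record. `species_profiles()` therefore apportions a dataset's
downloaded records over its species proportionally to stored records.
This preserves every dataset's download total exactly and is the neutral
assumption when within-dataset species preference is unobserved, but it
cannot recover genuine within-dataset preference; `usage_crown_indicator()`
accepts any externally supplied profile table for portals that do log
species-level downloads.

The **brute-force adjustment** (`value × r / 10⁶`) rescales impact-type
values by holdings in millions of records so that ultra-large publishers
rank apart from small ones; and publishers are classed by dataset number
as small (< 10), medium (10–100), large (101–300) or ultra-large (> 300).
The verbal class ranges overlap at the decade boundaries; the package
fixes 10 and 100 as medium and 300 as large, in one constant table.

## The synthetic generator

Nothing in the package requires a live portal: `simulate_usage()` draws an
inventory and an event log with the structural features the indicators
assume, plus the exact per-unit counts it injected, so the counting
pipeline can be tested against ground truth rather than against itself.

What it emulates, and the defaults (chosen once as desk-scale magnitudes
consistent with observed portal behaviour):

* **Long-tailed holdings.** Datasets per publisher and records per dataset
  are capped Pareto draws (20 publishers; records per dataset with floor
  40, shape 0.65, cap 30 000). Under these defaults the top decile of
  datasets holds well over half of all records, the concentration shape
  real occurrence holdings show.
* **Bounce-dominated traffic.** Each of the 500 visitor keys emits a
  Poisson(20) number of events (≈10 000 events); an event is a
  metadata-only bounce with probability 0.66.
* **Search- vs download-sized retrievals.** Records touched per event are
  lognormal: search events centre on a few tens of records (median 25),
  download events on a few hundred (median 300) — matching the observed
  ranges of roughly 18–50 records per search and 190–900 per download.
  One record-touching event in ten is a download.
* **Dataset-scoped record identifiers** (`"<dataset>:<index>"`), always
  generated, so the unique-record scores $U/r$ and $I/r$ are testable even
  though real portals expose them only internally.
* Event targets are drawn proportionally to dataset size, and touches are
  capped at the dataset's holdings.

Randomness is seeded per stage (structure, species, events, timestamps)
by a fixed label table derived from one root seed, so adding a new random
consumer never perturbs existing stages, and a fixed seed reproduces
output files byte for byte.

What it does **not** emulate: diurnal or seasonal cycles, crawler
traffic, within-dataset species preference in downloads, cross-dataset
duplicate records, or growth of holdings during a window. Passing tests on
synthetic data therefore demonstrate correctness of counting, aggregation
and the indicator algebra under the stated traffic model — not that real
portal logs satisfy that model.

## Numerical and degenerate-input policy

* Undefined ratios are `NA` with a reason (warning) where user-facing;
  impossible states ($U > r$, negative counts, non-positive session gaps,
  overlapping windows, duplicate dataset ids, profile species missing from
  a baseline) are errors that name the offending values.
* Malformed log lines are counted and reported per line, never silently
  dropped; unknown event types are rejected against a closed vocabulary.
* Rank-table ties are broken by unit id, so outputs are permutation
  invariant; UIF ties in the annual report break by stored records, then
  unit id.
* The Gini coefficient uses the standard sorted-sum formula and is checked
  against an $O(n^2)$ pairwise-difference oracle. No power-law exponent is
  fitted to rank tables: the long tail is summarized (top-$k$ share,
  Gini), not modelled.
* Problem sizes in the test suite are desk-scale by design: the reference
  tables are exact single-row computations; oracle-equality runs use 20
  seeded configurations of a few hundred events each; calibration checks
  use the ~10 000-event default.

## Known limitations

* Duplicate-record handling across datasets requires record identifiers;
  without them aggregation over publishers within a country can overstate
  $r(u)$ (flagged, not corrected).
* The apportionment estimator behind `species_profiles()` is exact at the
  dataset level but uninformative about within-dataset species preference.
* Indicators carry no uncertainty estimates; they are census-style counts
  of a log, not samples.
* Robot and crawler traffic is not detected beyond bounce removal.
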