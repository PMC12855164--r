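---
title: "Post-processing replicated eDNA metabarcoding surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing replicated eDNA metabarcoding surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednasurvey)
```

## The problem this package addresses

Environmental DNA (eDNA) metabarcoding surveys of terrestrial vertebrates —
for instance at savanna waterholes — collect many replicate samples (water,
sediment, soil) per location and day, amplify them with one or more
universal 12S rRNA primer pairs, and assign the resulting amplicon sequence
variants to taxa against a reference database. Everything downstream of that
assignment step is where most analytical decisions live, and it is what
`ednasurvey` implements:

1. **Plausibility filtering** of assigned taxa against a regional occurrence
   catalog, with reassignment of non-documented taxa to a unique documented
   congener and exclusion of ambiguous, unmatchable, or anthropogenic
   detections — with a complete audit trail.
2. **Pooling** replicate samples into *sampling events* (one substrate, one
   location, one day) and recording per-event positive-replicate counts.
3. **Descriptive statistics**: richness by grouping, shared/exclusive
   species, detection frequencies, rarity classes, positives-per-event
   distributions, and Jaccard/Bray–Curtis distance matrices for downstream
   ordination or PERMANOVA (which are deliberately *not* reimplemented here;
   the package exports tidy matrices for `vegan` and friends).
4. **Sampling-design evaluation**: permutation species-accumulation curves
   and the comparison of a hypothetical mixed-substrate design (k replicates
   of water plus k of sediment per day) against single-substrate designs.
5. A **synthetic survey generator** with known truth, so every stage above
   is testable without sequencing data.

## The curation rule

Let `D` be the set of species documented in the study region (e.g., compiled
from GBIF occurrence records) and, for each species, let a reference catalog
record whether the metabarcoding marker has a published sequence. Each
distinct assigned taxon `(name, rank)` receives exactly one decision, in
fixed precedence:

1. names on the **blocklist** (domestic animals, humans, anthropogenic food
   input) are excluded;
2. names with a configured **override** are reassigned to the override
   target (the shipped example is the re-classification of wolf assignments
   to the black-backed jackal *Lupulella mesomelas*, an abundant resident
   with thin reference coverage);
3. a species-rank name in `D` is **accepted**;
4. otherwise the congener set of the name's genus within `D` is resolved
   (for genus-rank input: all documented species of the genus) and an
   ambiguity criterion is applied: exactly one candidate → **reassign**;
   zero → **exclude** (no congener); several → **exclude** (ambiguous).

The ambiguity criterion has two selectable variants, because survey
practice supports both readings. `documented_congener_unique` (the default)
requires the genus to have exactly one documented species.
`unreferenced_congener_unique` counts only documented congeners *lacking* a
marker reference — the reasoning being that a misassignment driven by a
reference gap can only have come from an unreferenced congener. The two
variants differ exactly on the reference-gap case (several documented
congeners, one unreferenced), and the audit records both congener counts for
every decision so the choice is always auditable. Species with unknown
reference status are treated as lacking a reference when candidates are
counted, which mirrors how reference-gap lists are compiled; the query
itself (`has_reference()`) keeps `NA` distinct from `FALSE`.

Two normalization choices worth knowing: trinomial (subspecies) names are
truncated to the binomial before lookup, because occurrence catalogs are
binomial; and a flat alias table handles synonyms (e.g., *Canis mesomelas* →
*Lupulella mesomelas*) during canonicalization rather than in the decision
logic.

## Pooling and the combined-primer rule

A sampling event pools all replicates of one substrate at one location on
one day (typical replication: 8 for water and sediment, 6 for soil; any
positive count is accepted). `positives[s, e]` counts the distinct
replicates of event `e` detecting species `s`. For the combined two-primer
dataset, a replicate is positive if *either* primer detects the species in
it — the union at replicate level, then the count. Pooling at event level
instead would give the same incidence but could only increase positives
counts; the replicate-level union is the weakest assumption and is the
package's documented choice. Event identity is the (location, substrate,
date) triple; an `event_id` column, when present, takes precedence.

Genus-rank rows are rejected by `pool_by_event()`: the final dataset is
species-level, so assignment tables must pass `apply_filter()` first.

## Detection statistics

*Detection frequency* is the proportion of sampling events detecting a
species. The overall denominator is every event in the matrix, across
substrates; per-substrate frequencies use the substrate's own events. A
species is *rare* when its overall frequency is strictly below 0.1 (a
frequency of exactly 0.1 is abundant). Overlap summaries use exact set
arithmetic, and percentages of the union are rounded to the nearest integer
with ties away from zero (so a shared count of 45 out of a 95-species union
reports 47%). Jaccard distances are computed on incidence and Bray–Curtis on
positive-replicate counts — not read counts, which are decorative after
pooling — by delegating to `vegan::vegdist`; the single convention added on
top is that two events with no detections at all are at distance 0 (with a
warning), where the formula is undefined.

## Accumulation curves and design comparison

`accumulation_curve()` permutes the event order, takes cumulative distinct
species counts, and reports the mean and a confidence band per number of
events. With at most 7 events all K! orderings are enumerated, making the
means exact; otherwise 1000 random orderings are drawn by default. The
default band is the percentile interval across orderings, which avoids a
normality assumption; a mean ± 1.96·SD band (`ci_method = "sd"`) is offered
for parity with `vegan::specaccum`, whose exact means the package's
exhaustive means reproduce.

The mixed-substrate comparison first finds *paired days* — (location, date)
pairs with full replicate sets in both water and sediment — then, for each
day, draws `k_sub` replicates per substrate without replacement and pools
them into one hypothetical mixed event. A single draw is the default
(matching how such a hypothetical dataset is usually realized once), with
`n_draws > 1` available because a single draw is seed-sensitive; summaries
are then averaged over draws. When `k_sub` equals the full replicate count
the mixed event is exactly the union of the two single-substrate events,
which is also one of the package's invariant tests.

`volume_richness_table()` exports (event, total filtered volume, richness)
rows for water events; fitting a negative-binomial regression to them is
left to `MASS::glm.nb` or similar.

## The synthetic survey generator

The generator is a *test harness*, not an ecological claim. It is the
simplest generative structure consistent with the statistics above — a
two-level Bernoulli hierarchy:

* event level: species `s` has detectable DNA at event `e` with probability
  `psi_s * m_{s, season(e)}` (availability times a season multiplier);
* replicate level: given availability, replicate `r` under primer `q`
  detects `s` with probability `p_{s, substrate} * a_{s,q} * v(r)`, where
  `v(r)` is an optional filtered-volume effect for water replicates.

All uniform variates are drawn in a fixed order whose dimensions depend only
on the survey layout, never on parameter values. Raising any capture
probability under the same seed therefore re-uses the same uniforms and can
only add detections — the monotonicity the property tests rely on. Identical
config and seed give byte-identical tables. Read counts are drawn from a
shifted geometric distribution and carry no analytical weight downstream.

The `paper_like` preset fixes the study conditions the package is tested
under: a 95-species community at three waterholes over a wet and a dry
season, 8 sampling days per (location, substrate, season) block for water
and sediment, and dry-season soil trail blocks of 4 days with 6 replicates
(108 events in total). Species parameters are expanded once from fixed
hyperdistributions under an internal seed, so the preset is a deterministic
object: availability `psi ~ Beta(2, 1)`, a long-tailed per-replicate capture
base `p ~ Beta(0.8, 8)`, substrate affinities of 0.5–1 for water and
sediment and 0.1–0.7 for soil, a preferred season per species (multiplier 1,
the other season 0.4–1), and per-primer amplification indicators at 0.8
(conditioned so every species amplifies with at least one primer) times an
efficiency of 0.6–1. These choices produce overall detection frequencies
spanning roughly 0.01–0.85 with a long rare tail, partial primer overlap,
and — because per-replicate capture is low for most species — a
positives-per-event distribution with mode 1 in water and sediment, the
patchiness signature of waterhole eDNA. The default volume model (mean
460 ml, SD 100, slope 0) makes the analytic event-level detection
probability exact:

```
d(s | substrate, season, R replicates)
  = psi * m * (1 - (1 - p_rep)^R),   p_rep = 1 - (1 - p*a1)(1 - p*a2)
```

`recover_detection_params()` compares empirical frequencies against this
expression per (substrate, season) stratum and reports the bias and the
Monte-Carlo standard error `sqrt(d(1-d)/n_events)`; at a survey scale of
~2000 events, well over 95% of species–strata fall within 3 standard
errors. What the generator does *not* emulate: eDNA transport and decay,
read-level error (chimeras, index hopping), spatial autocorrelation between
waterholes, and secondary DNA input by vectors. Passing tests on synthetic
surveys therefore validate the *arithmetic* of the pipeline, not the
field realism of any particular survey.

The challenge generator (`generate_challenge()`) injects labels realizing
each curation scenario — documented accepts, reference-gap misassignments,
unique-congener reassignments, ambiguous and blocklisted taxa, overrides —
with the expected decision recorded under both ambiguity criteria, so filter
correctness is checked against ground truth rather than against itself.

## Numerical choices and degenerate inputs

* Percentile CIs use `stats::quantile` type 7; curve bands are clipped so
  `lower <= mean <= upper` holds even in degenerate cases.
* The positives-per-event mode takes the smallest value on ties.
* Events with zero detections are retained in all denominators (they are
  real sampling effort); all-zero distance pairs use the 0 convention above.
* `classify_taxon` on a species-rank name with no genus part excludes with a
  warning rather than erroring, so one malformed label cannot abort a run.
* Empty assignment tables flow through `apply_filter` to empty outputs;
  empty catalogs are a hard error.
* Exhaustive permutation enumeration switches on at K ≤ 7 (5040 orderings);
  problem sizes in the package's own test suite are chosen so exact oracles
  stay enumerable (≤ 10 species × ≤ 10 events for set statistics).

## Pipeline and provenance

`run_pipeline()` executes simulate → filter → pool → stats → design →
report against one output directory, derives per-stage seeds from the
master seed, and writes a `manifest.json` with version, seeds, parameters,
and md5 digests of every artifact. Reruns with the same config and seed
reproduce all statistical outputs byte-identically; manifests differ only
in timestamps. The exported functions are the package's interface; the
pipeline stages correspond one-to-one to the steps a survey analysis
script would run.

## Known limitations

* The filter matches names exactly after canonicalization; fuzzy matching
  and sequence-level re-classification are out of scope.
* Catalog provenance (GBIF query filters, reference-database versions) is
  the user's responsibility; the package consumes catalogs as files.
* Bray–Curtis on positive-replicate counts saturates at the replicate
  count; surveys with very uneven replication should interpret it with
  care.
* The mixed-design comparison assumes the two substrates were collected on
  the same days; days failing the replicate threshold are dropped, not
  imputed.
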