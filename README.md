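# ednasurvey

Post-processing and sampling-design evaluation for replicated environmental
DNA (eDNA) metabarcoding surveys — the kind that monitor terrestrial
vertebrates by sampling water, sediment, and soil at savanna waterholes with
multiple universal 12S rRNA primer pairs.

The package starts where read processing and taxonomic assignment stop. It
is written for ecologists who have per-sample taxon tables and need, with a
full audit trail:

* **plausibility filtering** of assigned taxa against a regional occurrence
  catalog — accept documented species, reassign a non-documented taxon to
  its unique documented congener, exclude ambiguous matches and blocklisted
  (domestic/anthropogenic) detections, apply justified overrides;
* **event pooling** — replicates of one substrate at one location on one day
  form a *sampling event*; the species-by-event matrix records how many
  replicates were positive;
* **detection statistics** — richness by any grouping, shared/exclusive
  species, detection frequencies (proportion of events detecting a species)
  with a rare/abundant split at 0.1, positives-per-event distributions, and
  Jaccard / Bray–Curtis distance matrices shaped for `vegan`;
* **design evaluation** — permutation species-accumulation curves (exact
  enumeration up to 7 events, percentile confidence bands) and the
  mixed-substrate design (k water + k sediment replicates per day) compared
  against single-substrate sampling on the same paired days;
* a **synthetic survey generator** with known truth — a two-level Bernoulli
  model (event-level availability × replicate-level capture, with substrate,
  season, primer, and filtered-volume effects) plus taxonomy-challenge
  tables — so the whole pipeline is testable end to end.

## The model at the core

For species *s* in an event of substrate *sub*, season *sea*, with *R*
replicates and primers *q* ∈ {12SV5, MiMammal}:

```
P(event detects s) = psi_s * m_{s,sea} * (1 - (1 - p_rep)^R)
p_rep              = 1 - (1 - p_{s,sub} * a_{s,1}) (1 - p_{s,sub} * a_{s,2})
```

Low per-replicate capture probabilities `p` make the number of positive
replicates per detection concentrate at 1 — the patchiness signature of
eDNA in terrestrial systems — and that is what the shipped `paper_like`
preset reproduces. The curation rule, the pooling conventions, and every
statistic are described in the methods vignette
(`vignettes/edna-survey-postprocessing.Rmd`).

## Worked example

```r
library(ednasurvey)

cfg  <- paper_like_config()                 # 95 species, 108 events
sim  <- generate_survey(cfg, seed = 42)

occ  <- occurrence_catalog(unique(sim$assignments$taxon_name))
ref  <- reference_catalog(occ$documented_species,
                          rep(TRUE, length(occ$documented_species)))
filt <- apply_filter(sim$assignments, occ, ref, curation_rules())
mat  <- pool_by_event(filt$detections, sim$samples, "combined")
mat
#> detection_matrix: 88 species x 108 sampling events (scope: combined )
#>   substrates: sediment:48  soil:12  water:48
#>   total detections (incidences): 2522

richness(mat, "substrate")
#>   substrate n_events richness
#> 1  sediment       48       85
#> 2      soil       12       54
#> 3     water       48       84

overlap(mat, "substrate")
#> overlap over 3 levels; union = 88 species
#>      level richness exclusive
#> 1    water       84         2
#> 2 sediment       85         4
#> 3     soil       54         0
#> shared by all levels: 53 (60% of union)

positives_distribution(mat, by_substrate = TRUE)$water$mode
#> [1] 1

paired <- paired_days(sim$samples)          # days with 8 water + 8 sediment
b   <- build_mixed_design(filt$detections, sim$samples, paired,
                          k_sub = 4, seed = 42)
compare_designs(b$mixed, b$sediment, b$water,
                n_permutations = 200, seed = 42)
#> design comparison over 48 paired sampling events
#>          design n_events mean_event_richness sd_event_richness overall_richness
#> 1         mixed       48                27.7              3.78               84
#> 2 sediment_only       48                24.9              3.61               85
#> 3    water_only       48                24.7              3.52               84
```

Reading the output: 88 of the 95 simulated species were detected at least
once; sediment and water events carry similar richness while the 12
soil-trail events carry less; the detection mode of 1 positive replicate per
event reflects eDNA patchiness; and the hypothetical mixed 4+4 design yields
higher mean per-event richness than either single-substrate design built
from the same 48 paired sampling days.

`run_pipeline()` wires the same steps (simulate → filter → pool → stats →
design → report) into one output directory with a provenance manifest:

```r
run_pipeline(list(simulate = list(preset = "paper_like")), "run1", seed = 42)
```

Example catalogs, curation rules (including the wolf → black-backed jackal
override), and the survey preset ship under `inst/extdata/`.

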