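# Paper-like synthetic survey preset: a ~95-species vertebrate community
# sampled at three waterholes over a wet and a dry season, with 8 water and
# 8 sediment replicates per sampling event and dry-season soil trail events
# of 6 replicates. Species parameters are expanded deterministically from
# fixed hyperdistributions; see ?paper_like_config.
preset: paper_like
n_species: 95
events_per_combo: 8
include_soil: true
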