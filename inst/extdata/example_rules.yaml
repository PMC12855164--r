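# Example curation rules for a southern African waterhole survey.
# blocklist: domestic animals, humans, and anthropogenic food input.
# overrides: manually justified re-classifications (here, wolf assignments
# re-classified to the resident black-backed jackal, whose reference
# coverage is thin).
blocklist:
  - Homo sapiens
  - Bos taurus
  - Ovis aries
  - Capra hircus
  - Sus scrofa
  - Felis catus
  - Gallus gallus
  - Thunnus albacares
  - Salmo salar
overrides:
  Canis lupus: Lupulella mesomelas
aliases:
  Canis mesomelas: Lupulella mesomelas
ambiguity_mode: documented_congener_unique
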