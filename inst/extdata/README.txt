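amniote_tree.nwk / amniote_tip_codings.csv
  Editable group-level tree and discrete tip codings for the
  reptile/bird/mammal ancestral-state example (Testudines sister to
  Crocodylia+Aves; lobe-finned fish outgroup). The codings are binary
  presence/absence of each broad bile-salt compound type at >= 10% of the
  biliary pool, assembled from descriptive accounts of each group's biliary
  profile; they are an editable working hypothesis, not a published data
  table. "Aves" is coded from paleognath birds (C27 alcohols and trihydroxy
  C27 acids retained) plus the C24 acids of most other birds.

synthetic_profiles_example.csv
  Small synthetic species-profile table (long format) illustrating the
  reader/classifier; values are invented for demonstration.
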