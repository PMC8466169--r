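# Two-variety orchard: Tanche (production) with Cayon as pollinizer.
flowers_per_variety: 100
pollen_per_flower_per_day: 5
season_length: 25
receptive_days: 6
varieties:
  - name: Tanche
    dsi_group: G2
    pasi_pair: R2R3
    proportion: 0.8
    bloom_start: 3
    bloom_end: 14
  - name: Cayon
    dsi_group: G1
    pasi_pair: R1R4
    proportion: 0.2
    bloom_start: 3
    bloom_end: 14
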