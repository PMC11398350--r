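Synthetic toy dataset (not real occurrence data): a 12-species unit-height
tree with three thermally ordered forest biomes (T tropical, W warm
temperate, C cold temperate), tip affinity codes in {0,1,2,?} and an
include/exclude constraint table, mimicking the file structure of an
empirical biome-affinity study.
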