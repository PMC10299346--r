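genome	expansion_families
wheat	650
rice	494
maize	611
millet	600
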