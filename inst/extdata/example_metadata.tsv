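sample_id	biome	salinity	date
AQ1	aquatic	0.9	2023-04-02
AQ2	aquatic	3.8	2023-04-02
AQ3	aquatic	12.5	2023-04-16
AQ4	aquatic	21.0	2023-04-16
AIR1	airborne		2023-04-09
SED1	sediment		2023-04-09
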