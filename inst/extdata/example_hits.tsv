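taxon	term	identity	count
zotu_001	freshwater lake	99.6	34
zotu_001	soil	99.2	11
zotu_001	estuary	99.8	9
zotu_002	hypersaline lake	99.4	21
zotu_003	marine biome	99.9	18
zotu_003	soil	99.1	14
zotu_003	freshwater lake	99.0	8
zotu_003	sediment	98.6	6
zotu_004	estuary	99.3	12
zotu_004	freshwater lake	99.5	7
zotu_005	soil	99.7	25
zotu_006	hypersaline lake	99.2	16
zotu_006	saline evaporation pond	99.6	5
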