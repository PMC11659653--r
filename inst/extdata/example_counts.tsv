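taxon	AQ1	AQ2	AQ3	AQ4	AIR1	SED1
zotu_001	210	180	40	5	12	3
zotu_002	0	15	160	240	0	0
zotu_003	55	60	48	52	140	110
zotu_004	130	90	10	0	0	25
zotu_005	5	5	2	3	48	0
zotu_006	0	0	140	100	0	2
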