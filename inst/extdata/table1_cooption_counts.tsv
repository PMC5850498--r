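lineage_id	family_id	n_cooptions
ak-1P1	ak	8
alaat-1P5	alaat	3
aspat-2P3	aspat	3
aspat-3P4	aspat	3
dit-2P3	dit	1
nadpmdh-1P1	nadpmdh	5
nadpmdh-3P4	nadpmdh	1
nadpme-1P4	nadpme	7
nhd-1P1	nhd	5
pck-1P1	pck	5
pepck-1P1	pepck	1
ppa-1P2.1	ppa	6
ppc-1P3	ppc	8
ppc-1P6	ppc	2
ppdk-1P2	ppdk	10
ppt-1P5	ppt	4
sbas-1P1	sbas	8
tpt-1P1	tpt	10
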