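# Packaged snapshot of known mitochondrial polymorphisms and
# disease-associated sites (sources: MITOMAP, dbSNP v138, HapMap phase 3).
# Offline snapshot -- no live database queries. Positions are 1-based rCRS;
# for insertions the position is the 5' flanking base and ref is empty.
# snapshot_version: 2017-static-1
position	ref	alt	var_type	source	disease_flag	note
73	A	G	SNV	dbSNP	FALSE	common control-region polymorphism
146	T	C	SNV	dbSNP	FALSE	control region
152	T	C	SNV	dbSNP	FALSE	control region
195	T	C	SNV	dbSNP	FALSE	control region
263	A	G	SNV	dbSNP	FALSE	near-universal control-region polymorphism
315		C	insertion	MITOMAP	FALSE	C-tract length polymorphism (302-315 microsatellite)
489	T	C	SNV	dbSNP	FALSE	control region
750	A	G	SNV	dbSNP	FALSE	RNR1
1438	A	G	SNV	dbSNP	FALSE	RNR1
2706	A	G	SNV	dbSNP	FALSE	RNR2
3010	G	A	SNV	MITOMAP	FALSE	RNR2 haplogroup marker
4769	A	G	SNV	dbSNP	FALSE	ND2
7028	C	T	SNV	dbSNP	FALSE	CO1 haplogroup marker
8860	A	G	SNV	dbSNP	FALSE	ATP6
9055	G	A	SNV	HAPMAP	FALSE	ATP6
10398	A	G	SNV	MITOMAP	TRUE	ND3; associated with breast and endometrial cancer risk
10400	C	T	SNV	HAPMAP	FALSE	ND3 haplogroup marker
11719	G	A	SNV	dbSNP	FALSE	ND4
12308	A	G	SNV	MITOMAP	FALSE	TRNL2
13708	G	A	SNV	MITOMAP	TRUE	ND5; LHON-associated
14766	C	T	SNV	dbSNP	FALSE	CYB
15326	A	G	SNV	dbSNP	FALSE	CYB
16126	T	C	SNV	HAPMAP	FALSE	control region
16189	T	C	SNV	MITOMAP	TRUE	hypermutable polyC stretch; associated with breast and endometrial cancer risk
16223	C	T	SNV	HAPMAP	FALSE	control region
16311	T	C	SNV	HAPMAP	FALSE	control region
16519	T	C	SNV	dbSNP	FALSE	control region
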