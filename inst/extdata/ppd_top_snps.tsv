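snp_id	chrom	pos	region	ref	alt	gt_cases	gt_controls
rs791053563	SSC11	70808545	intron	G	C	0/0:4	1/1:11,0/1:2
rs709805150	SSC11	42738578	IGR	C	T	1/1:3,0/0:1	0/0:13
rs711914258	SSC11	71068779	intron	T	C	1/1:4	0/0:11,0/1:1,1/1:1
rs342954583	SSC11	71068862	intron	C	G	1/1:4	0/0:11,0/1:1,1/1:1
rs336503862	SSC11	71068919	intron	C	G	1/1:4	0/0:11,0/1:1,1/1:1
rs320384943	SSC11	70801220	intron	T	C	1/1:4	0/0:11,1/1:2
SSC11:70439379	SSC11	70439379	exon	A	G	1/1:4	0/0:9,0/1:4
SSC11:71068754	SSC11	71068754	intron	A	G	1/1:4	0/0:10,0/1:2,1/1:1
rs335010523	SSC11	71068848	intron	T	A	1/1:4	0/0:10,0/1:2,1/1:1
rs325300849	SSC11	71068895	intron	A	G	1/1:4	0/0:10,0/1:2,1/1:1
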