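tissue	condition	gene_set	ci_low	ci_high
muscle	3d	interpeak	0.758	1.017
muscle	15d	interpeak	1.023	1.401
muscle	30d	interpeak	1.149	1.562
muscle	3d	peak	3.349	3.739
muscle	15d	peak	3.681	4.075
muscle	30d	peak	3.817	4.230
muscle	lateonset_15d	interpeak	0.295	0.315
muscle	lateonset_15d	peak	0.320	0.345
muscle	lateonset_30d	interpeak	0.430	0.452
muscle	lateonset_30d	peak	0.468	0.493
head	3d	interpeak	1.907	2.027
head	30d	interpeak	2.263	2.402
head	3d	peak	6.912	7.146
head	30d	peak	6.985	7.217
head	WT_30d	interpeak	0.737	0.783
head	PRC2mut_30d	interpeak	0.4498	0.4787
head	WT_30d	peak	2.193	2.268
head	PRC2mut_30d	peak	1.787	1.858
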