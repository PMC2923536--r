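# Raw columns of the eight TILLING assays on the EMS-mutagenized B. rapa
# R-o-18 population: six amplicons screened on the 0.3% EMS population and
# two on the 0.4% population. GC percentages are the integer values as
# reported for each amplicon. Derived quantities (density, per-plant load,
# expected yield) are recomputed by summarize_assays(); the published table
# prints "1/358" for the BraA.RPL.c 0.4% density where the raw columns give
# 1001*2304/40 = 57,658 bp, i.e. 1/58 (a typo, not stored here since only
# raw columns are).
gene	ems_pct	length_bp	gc_pct	mutations	screened	population
BraA.RPL.a	0.3	1007	47	21	768	6912
BraA.RPL.b	0.3	1072	45	149	4608	6912
BraA.RPL.c	0.3	1001	47	132	4608	6912
BraA.IND.a	0.3	1004	41	35	3072	6912
BraA.MET1.a	0.3	1104	48	94	3072	6912
BraA.MET1.b	0.3	1007	47	89	3072	6912
BraA.RPL.b	0.4	1072	45	57	2304	2304
BraA.RPL.c	0.4	1001	47	40	2304	2304
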