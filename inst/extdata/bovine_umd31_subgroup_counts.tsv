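# Per-subgroup germline V-gene accounting for the bovine TRA/TRD locus as
# annotated on the UMD3.1 assembly (42 subgroups, 371 genes; percent
# functional uses all genes of the subgroup, incomplete included).
subgroup	total	functional	pseudogene	incomplete
TRAV1	1	1	0	0
TRAV2	7	5	2	0
TRAV3	7	7	0	0
TRAV4	3	2	1	0
TRAV5	2	2	0	0
TRAV6	4	0	3	1
TRAV8	14	6	8	0
TRAV9	11	1	9	1
TRAV10	6	3	3	0
TRAV11	6	0	6	0
TRAV12	6	5	1	0
TRAV13	11	8	2	1
TRAV14	9	4	4	1
TRAV16	2	2	0	0
TRAV17	3	1	2	0
TRAV18	8	3	5	0
TRAV19	7	5	2	0
TRAV20	5	5	0	0
TRAV21	4	3	1	0
TRAV22	29	14	14	1
TRAV23	24	4	20	0
TRAV24	10	1	8	1
TRAV25	22	11	10	1
TRAV26	39	22	13	4
TRAV27	1	1	0	0
TRAV28	4	3	1	0
TRAV29	3	2	1	0
TRAV33	6	2	4	0
TRAV34	3	0	3	0
TRAV35	1	1	0	0
TRAV36	1	1	0	0
TRAV37	2	0	0	2
TRAV38	6	5	1	0
TRAV39	2	1	1	0
TRAV41	1	1	0	0
TRAVX	29	23	5	1
TRAVY	7	7	0	0
TRDV1	60	48	8	4
TRDV2	1	1	0	0
TRDV3	1	1	0	0
TRDVb3	2	2	0	0
TRDVY	1	1	0	0
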