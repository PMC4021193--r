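gene_a	gene_b	n_anchors	mean_ks	sd_ks	age_my
GmEXPA22	GmEXPA49	6	0.100	0.012	8
GmEXPA8	GmEXPA47	15	0.119	0.054	10
GmEXPA4	GmEXPA32	10	0.145	0.024	12
GmEXPA30	GmEXPA34	20	0.149	0.054	12
GmEXPA24	GmEXPA27	18	0.157	0.118	13
GmEXPA11	GmEXPA15	15	0.175	0.141	14
GmEXPA6	GmEXPA31	13	0.177	0.213	14
GmEXPA9	GmEXPA13	19	0.188	0.172	15
GmEXPA21	GmEXPA43	17	0.202	0.166	17
GmEXPA12	GmEXPA36	16	0.205	0.096	17
GmEXPA2	GmEXPA23	20	0.239	0.253	20
GmEXPA26	GmEXPA38	14	0.254	0.219	21
GmEXPA1	GmEXPA3	5	0.270	0.132	22
GmEXPA18	GmEXPA28	5	0.296	0.266	24
GmEXPA17	GmEXPA29	4	0.300	0.179	25
GmEXPA8	GmEXPA49	4	0.453	0.085	37
GmEXPA16	GmEXPA35	5	0.477	0.346	39
GmEXPA47	GmEXPA49	4	0.515	0.139	42
GmEXPA22	GmEXPA47	8	0.531	0.118	44
GmEXPA8	GmEXPA22	8	0.539	0.132	44
GmEXPA24	GmEXPA34	9	0.598	0.189	49
GmEXPA27	GmEXPA34	9	0.613	0.180	50
GmEXPA24	GmEXPA30	11	0.617	0.158	51
GmEXPA27	GmEXPA30	11	0.626	0.155	51
GmEXPA6	GmEXPA38	4	0.633	0.257	52
GmEXPA2	GmEXPA36	6	0.650	0.158	53
GmEXPA6	GmEXPA26	4	0.650	0.177	53
GmEXPA26	GmEXPA31	4	0.680	0.163	56
GmEXPA23	GmEXPA36	5	0.685	0.135	56
GmEXPA2	GmEXPA12	7	0.708	0.099	58
GmEXPA13	GmEXPA37	7	0.710	0.102	58
GmEXPA9	GmEXPA37	7	0.763	0.112	63
GmEXPA12	GmEXPA23	6	0.768	0.078	63
GmEXPA21	GmEXPA45	3	0.790	0.207	65
GmEXPA43	GmEXPA45	3	0.817	0.266	67
GmEXPB8	GmEXPB9	16	0.169	0.077	14
GmEXPB3	GmEXPB7	6	0.397	0.277	33
GmEXLA1	GmEXLA2	23	0.167	0.072	14
GmEXLB3	GmEXLB8	19	0.176	0.117	14
GmEXLB5	GmEXLB12	8	0.191	0.165	16
GmEXLB7	GmEXLB15	7	0.202	0.149	17
GmEXLB6	GmEXLB14	8	0.211	0.179	17
GmEXLB2	GmEXLB9	15	0.236	0.216	19
GmEXLB2	GmEXLB15	3	0.447	0.029	37
GmEXLB9	GmEXLB15	3	0.503	0.068	41
GmEXLB3	GmEXLB6	3	0.513	0.093	42
GmEXLB3	GmEXLB12	6	0.630	0.117	52
GmEXLB4	GmEXLB8	4	0.685	0.227	56
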