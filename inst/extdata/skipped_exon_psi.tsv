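exon_id	chrom	start	end	strand	transcript_id	gene	E15	E18	P0	P3	P6	P9
ENSMUSE00000334942	19	57051130	57051234	-	ENSMUST00000111559	Ablim1	NA	0.13	0.61	0.729	0.66	0.612
ENSMUSE00000668725	3	148849766	148849804	-	ENSMUST00000197567	Adgrl2	0.202	0.24	0.61	NA	0.57	0.611
ENSMUSE00001324776	1	82891460	82891507	+	ENSMUST00000190052	Agfg1	0.232	0.18	0.41	0.532	0.48	0.489
ENSMUSE00001039657	18	6057517	6057591	-	ENSMUST00000182066	Arhgap12	0.289	0.32	0.82	NA	NA	NA
ENSMUSE00000700987	2	10056770	10056806	-	ENSMUST00000114897	Atp5c1	0.822	0.76	0.55	0.55	0.62	0.574
ENSMUSE00000230008	18	32426224	32426352	+	ENSMUST00000091967	Bin1	NA	0.68	0.18	NA	NA	NA
ENSMUSE00000217920	9	70004306	70004341	+	ENSMUST00000034754	Bnip2	NA	0.5	0.9	0.806	NA	0.845
ENSMUSE00000736151	10	127064202	127064453	+	ENSMUST00000133115	Cdk4	0.959	0.96	0.8	NA	NA	NA
ENSMUSE00000691476	5	112251747	112251797	-	ENSMUST00000112385	Cryba4	0.974	0.98	NA	0.994	0.99	0.99
ENSMUSE00000311733	14	47726471	47726554	+	ENSMUST00000022391	Ktn1	NA	0.24	0.5	0.476	NA	0.517
ENSMUSE00000440236	6	93680789	93680877	-	ENSMUST00000204347	Magi1	0.118	0.09	NA	NA	0.48	0.655
ENSMUSE00000667965	7	143518850	143518885	-	ENSMUST00000072727	Nap1l4	0.477	0.42	0.29	0.228	0.25	0.245
ENSMUSE00001311933	2	105695306	105695456	+	ENSMUST00000111082	Pax6	0.995	1	0.94	0.993	1	NA
ENSMUSE00000317905	15	93452117	93452173	+	ENSMUST00000068457	Pphln1	0.151	0.07	0.57	0.356	0.5	0.639
ENSMUSE00000635082	9	86790056	86790139	-	ENSMUST00000074468	Snap91	NA	0.85	0.27	0.248	0.2	NA
ENSMUSE00001196118	11	80393084	80393176	+	ENSMUST00000123726	Zfp207	0.368	NA	0.67	NA	0.61	0.593
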