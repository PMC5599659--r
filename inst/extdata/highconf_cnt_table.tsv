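filter_set	gene_id	transcript_id	chrom	start	end	length_bp	strand	phastcons	novelty_score
broad	MSTRG.10752	MSTRG.10752.1	16	91113662	91114155	493	.	0.997	100
broad	MSTRG.11071	MSTRG.11071.1	17	16557283	16557630	347	.	0.997	100
broad	MSTRG.11709	MSTRG.11709.2	17	39636629	39637143	514	-	0.997	100
broad	MSTRG.13417	MSTRG.13417.2	19	17926989	17927998	1009	+	0.993	100
broad	MSTRG.9039	MSTRG.9039.1	15	31655084	31655385	301	.	0.990	100
broad	MSTRG.17446	MSTRG.17446.1	3	104752371	104752702	331	-	0.989	100
broad	MSTRG.30048	MSTRG.30048.1	X	146176602	146177068	466	+	0.989	100
broad	MSTRG.12849	MSTRG.12849.1	18	64611849	64612445	596	-	0.989	100
broad	MSTRG.1816	MSTRG.1816.1	1	178299808	178300378	570	+	0.987	100
broad	MSTRG.18663	MSTRG.18663.1	4	83421622	83422080	458	-	0.987	100
broad	MSTRG.6455	MSTRG.6455.1	12	102866597	102867299	702	.	0.984	100
broad	MSTRG.12840	MSTRG.12840.1	18	63543865	63545205	1340	+	0.981	100
broad	MSTRG.21639	MSTRG.21639.1	5	127954976	127955377	401	.	0.978	100
broad	MSTRG.8143	MSTRG.8143.1	14	33428605	33429024	419	.	0.973	100
broad	MSTRG.13495	MSTRG.13495.1	19	25346816	25347223	407	.	0.973	100
broad	MSTRG.15865	MSTRG.15865.1	2	157528311	157528617	306	.	0.970	100
broad	MSTRG.20543	MSTRG.20543.1	5	46415104	46415426	322	+	0.970	100
broad	MSTRG.6330	MSTRG.6330.1	12	86845755	86846203	448	.	0.970	100
broad	MSTRG.8249	MSTRG.8249.1	14	48695580	48695978	398	.	0.969	100
broad	MSTRG.7535	MSTRG.7535.1	13	91260953	91262729	1776	+	0.969	100
broad	MSTRG.18684	MSTRG.18684.1	4	87103424	87105078	1654	+	0.967	100
broad	MSTRG.18685	MSTRG.18685.1	4	87103426	87105078	1652	-	0.967	100
broad	MSTRG.6715	MSTRG.6715.1	13	8289064	8289370	306	.	0.966	100
broad	MSTRG.7905	MSTRG.7905.1	14	15949235	15949774	539	.	0.965	100
broad	MSTRG.7913	MSTRG.7913.1	14	16451876	16452185	309	.	0.953	100
specific	MSTRG.16504	MSTRG.16504.1	3	36117033	36117334	301	.	1.000	100
specific	MSTRG.18476	MSTRG.18476.1	4	53663579	53663885	306	.	0.993	100
specific	MSTRG.12840	MSTRG.12840.2	18	63543888	63544690	802	+	0.989	100
specific	MSTRG.444	MSTRG.444.1	1	52585218	52585601	383	.	0.988	100
specific	MSTRG.7901	MSTRG.7901.1	14	14447656	14448019	363	.	0.982	100
specific	MSTRG.25445	MSTRG.25445.1	7	127398616	127399037	421	.	0.980	100
specific	MSTRG.3390	MSTRG.3390.1	10	129665538	129665871	333	.	0.975	100
specific	MSTRG.6084	MSTRG.6084.1	12	72048695	72049032	337	.	0.975	100
specific	MSTRG.10567	MSTRG.10567.1	16	53985023	53985331	308	.	0.973	100
specific	MSTRG.10245	MSTRG.10245.1	16	23050282	23050873	591	.	0.973	100
specific	MSTRG.6777	MSTRG.6777.2	13	15119006	15119437	431	+	0.970	100
specific	MSTRG.26441	MSTRG.26441.1	8	72283729	72284163	434	.	0.969	100
specific	MSTRG.10714	MSTRG.10714.1	16	88682165	88682703	538	.	0.966	100
specific	MSTRG.25152	MSTRG.25152.1	7	107951379	107951776	397	.	0.963	100
specific	MSTRG.14539	MSTRG.14539.1	2	34648981	34649511	530	-	0.956	100
specific	MSTRG.6778	MSTRG.6778.2	13	15118406	15118934	528	+	0.956	100
specific	MSTRG.13452	MSTRG.13452.1	19	23166931	23168119	1188	.	0.956	100
specific	MSTRG.12890	MSTRG.12890.1	18	67920731	67921163	432	.	0.955	100
specific	MSTRG.13017	MSTRG.13017.1	18	90311445	90311766	321	.	0.952	100
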