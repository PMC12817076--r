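##gff-version 3
contig_01	annoclass	gene	498	1219	.	+	.	ID=p_g00001
contig_01	annoclass	mRNA	498	1219	.	+	.	ID=p_g00001.t1;Parent=p_g00001
contig_01	annoclass	CDS	498	617	.	+	0	Parent=p_g00001.t1
contig_01	annoclass	CDS	733	1219	.	+	0	Parent=p_g00001.t1
contig_01	annoclass	gene	1521	3148	.	-	.	ID=p_g00002_frag1
contig_01	annoclass	mRNA	1521	3148	.	-	.	ID=p_g00002_frag1.t1;Parent=p_g00002_frag1
contig_01	annoclass	CDS	1521	2014	.	-	0	Parent=p_g00002_frag1.t1
contig_01	annoclass	CDS	2246	2702	.	-	0	Parent=p_g00002_frag1.t1
contig_01	annoclass	CDS	2768	3148	.	-	0	Parent=p_g00002_frag1.t1
contig_01	annoclass	gene	3404	3717	.	-	.	ID=p_g00002_frag2
contig_01	annoclass	mRNA	3404	3717	.	-	.	ID=p_g00002_frag2.t1;Parent=p_g00002_frag2
contig_01	annoclass	CDS	3404	3717	.	-	0	Parent=p_g00002_frag2.t1
contig_01	annoclass	gene	4110	5460	.	+	.	ID=p_g00003
contig_01	annoclass	mRNA	4110	5460	.	+	.	ID=p_g00003.t1;Parent=p_g00003
contig_01	annoclass	CDS	4110	4594	.	+	0	Parent=p_g00003.t1
contig_01	annoclass	CDS	4895	5093	.	+	0	Parent=p_g00003.t1
contig_01	annoclass	CDS	5196	5460	.	+	0	Parent=p_g00003.t1
contig_01	annoclass	gene	8091	16211	.	+	.	ID=p_merged_0001
contig_01	annoclass	mRNA	8091	16211	.	+	.	ID=p_merged_0001.t1;Parent=p_merged_0001
contig_01	annoclass	CDS	8091	8481	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	8558	8905	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	8998	9099	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	9203	9666	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	9929	10208	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	10300	10486	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	10594	10733	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	10955	11234	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	12998	13137	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	13205	13334	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	13403	13791	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	14038	14424	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	14685	15179	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	15325	15751	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	CDS	15927	16211	.	+	0	Parent=p_merged_0001.t1
contig_01	annoclass	gene	11591	12470	.	-	.	ID=p_g00006
contig_01	annoclass	mRNA	11591	12470	.	-	.	ID=p_g00006.t1;Parent=p_g00006
contig_01	annoclass	CDS	11591	11927	.	-	0	Parent=p_g00006.t1
contig_01	annoclass	CDS	12045	12470	.	-	0	Parent=p_g00006.t1
contig_01	annoclass	gene	16998	19870	.	-	.	ID=p_g00008
contig_01	annoclass	mRNA	16998	19870	.	-	.	ID=p_g00008.t1;Parent=p_g00008
contig_01	annoclass	CDS	16998	17175	.	-	0	Parent=p_g00008.t1
contig_01	annoclass	CDS	17278	17450	.	-	0	Parent=p_g00008.t1
contig_01	annoclass	CDS	17598	17870	.	-	0	Parent=p_g00008.t1
contig_01	annoclass	CDS	18046	18522	.	-	0	Parent=p_g00008.t1
contig_01	annoclass	CDS	18643	19056	.	-	0	Parent=p_g00008.t1
contig_01	annoclass	CDS	19144	19482	.	-	0	Parent=p_g00008.t1
contig_01	annoclass	CDS	19596	19870	.	-	0	Parent=p_g00008.t1
contig_01	annoclass	gene	23369	27048	.	-	.	ID=p_g00010
contig_01	annoclass	mRNA	23369	27048	.	-	.	ID=p_g00010.t1;Parent=p_g00010
contig_01	annoclass	CDS	23369	23785	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	CDS	24004	24157	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	CDS	24366	24536	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	CDS	24767	25149	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	CDS	25296	25666	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	CDS	25949	26225	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	CDS	26511	26627	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	CDS	26910	27048	.	-	0	Parent=p_g00010.t1
contig_01	annoclass	mRNA	23369	27048	.	-	.	ID=p_g00010.t2;Parent=p_g00010
contig_01	annoclass	CDS	23369	23785	.	-	0	Parent=p_g00010.t2
contig_01	annoclass	CDS	24004	24157	.	-	0	Parent=p_g00010.t2
contig_01	annoclass	CDS	24767	25149	.	-	0	Parent=p_g00010.t2
contig_01	annoclass	CDS	25296	25666	.	-	0	Parent=p_g00010.t2
contig_01	annoclass	CDS	25949	26225	.	-	0	Parent=p_g00010.t2
contig_01	annoclass	CDS	26511	26627	.	-	0	Parent=p_g00010.t2
contig_01	annoclass	CDS	26910	27048	.	-	0	Parent=p_g00010.t2
contig_01	annoclass	gene	27535	30091	.	+	.	ID=p_g00011
contig_01	annoclass	mRNA	27535	30091	.	+	.	ID=p_g00011.t1;Parent=p_g00011
contig_01	annoclass	CDS	27535	28086	.	+	0	Parent=p_g00011.t1
contig_01	annoclass	CDS	28308	28572	.	+	0	Parent=p_g00011.t1
contig_01	annoclass	CDS	28714	29078	.	+	0	Parent=p_g00011.t1
contig_01	annoclass	CDS	29146	29353	.	+	0	Parent=p_g00011.t1
contig_01	annoclass	CDS	29578	29740	.	+	0	Parent=p_g00011.t1
contig_01	annoclass	CDS	29881	30091	.	+	0	Parent=p_g00011.t1
contig_01	annoclass	gene	30459	31932	.	+	.	ID=p_g00012
contig_01	annoclass	mRNA	30459	31932	.	+	.	ID=p_g00012.t1;Parent=p_g00012
contig_01	annoclass	CDS	30459	30805	.	+	0	Parent=p_g00012.t1
contig_01	annoclass	CDS	30977	31452	.	+	0	Parent=p_g00012.t1
contig_01	annoclass	CDS	31713	31932	.	+	0	Parent=p_g00012.t1
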