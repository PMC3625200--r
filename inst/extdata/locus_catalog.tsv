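no	locus	location	features	rec_rate	ltr5	internal	ltr3	internal2	ltr3b	provenance
1	K116	chr1:75842771-75849143	Inserted into human-specific L1PA2	0.7	968	4437	968			as printed
2	K102	chr1:155596457-155605636	-	1.3	968	7244	968			as printed
3	K120	chr2:130719538-130722650	Inserted into SD region	1.1	23	2129	961			as printed
4	K106	chr3:112743124-112752282	Polymorphic	0.4	960	7239	960			as printed
5	K121	chr3:125609302-125618439	Inserted into SD region	0.8	804	7530	804			as printed
6	K122	chr3:148281441-148285419	13 bp L1 sequence in 3' end of ERV, polymorphic	2.1	23	3920	23			as printed
7	K123	chr3:170955654-170955804	Non-classical insertion, HERV-K9 subfamily	1.5	0	143	0			as printed
8	K117	chr3:185280336-185289515	Inserted into SD region, polymorphic	2	968	7244	968			as printed
9	K124	chr4:161579938-161582439	Second HERV-K internal to 206 bp in first HERV-K internal of 3' end	0.9	968	1171	78	206	78	78 bp LTRs reversed per table footnote
10	K104	chr5:30486760-30496205	-	1.8	951	7535	960			as printed
11	K107	chr5:156084717-156093896	Polymorphic	0.6	968	7244	968			as printed
12	K125	chr6:74042982-74043123	Non-classical insertion	0.6	0	142	0			as printed
13	K109	chr6:78426662-78436083	Polymorphic	0.7	960	7502	960			as printed
14	K108	chr7:4622057-4640031	LTR-LTR homologous recombination, polymorphic	1.6	968	7535	968	7536	968	as printed
15	K126	chr7:104388369-104393269	13bp L1 sequence in 3' end of ERV	1.1	0	3921	967			967 bp LTR reversed per table footnote
16	K115	chr8:7355397-7364859	Inserted into SD region, polymorphic	0.9	960	7535	968			as printed
17	K127	chr8:140472149-140475259	-	2.7	23	2120	968			as printed
18	K128	chr10:101580569-101587739	-	0.1	23	6162	968			as printed
19	K118	chr11:101565794-101575259	Polymorphic	0.6	968	7530	968			as printed
20	K119	chr12:58721242-58730698	Polymorphic	0.3	968	7521	968			as printed
21	K129	chr12:111007843-111009348	-	0.6	968	515	23			as printed
22	K130	chr16:34231397-34234142	Non-classical insertion	0.1	0	1788	958			as printed
23	K131	chr17:6078917-6079053	Non-classical insertion	3.5	0	96	41			as printed
24	K132	chr19:28128498-28137384	Inserted into satellite DNA region of centromere	0.4	23	7546	995			as printed
25	K133	chr21:19933659-19941962	TSD contains partial LTR50, MIRb, and AT_rich	3	966	7081	257			as printed
26	K101	chr22:18926187-18935361	Inserted into SD region	3.3	968	7243	964			as printed
27	K103	chr10:27182399-27183366	Solitary LTR in hg19, inserted into SD region, polymorphic	0.9	968	7245	968			as printed
28	K113	chr19:21841536-21841541	Absence in hg19, inserted into SD region, polymorphic	0.1	968	7536	968			as printed
29	K134	chr12:55727215-55728183	Solitary LTR in hg19, polymorphic	1.1	969	7243	968			as printed
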