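type	locus	position	ltr5	ltr3	internal	comment	stop_region	provenance
I	K101	chr22:18926187-18935361	968	964	7243	In frame pol broken	TGA/pro	as printed
I	K102	chr1:155596457-155605636	968	968	7244	In frame pol-env fusion	TGA/gag	end coordinate corrected from 15605636 (locus table agrees)
I	K103	chr10:27182399-27183366	968	968	7245	In frame pol-env fusion/env broken	-	as printed
I	K106	chr3:112743124-112752282	960	960	7239	In frame env broken	-	as printed
I	K107	chr5:156084717-156093896	968	968	7244	In frame pol-env fusion	-	as printed
I	K117	chr3:185280336-185289515	968	968	7244	In frame pol-env fusion/env broken	TAG/env	start coordinate corrected from 18528336 (locus table agrees)
I	K133	chr21:19933659-19941962	966	257	7081	In frame pol-env fusion/env broken	TAG, TGA/gag, pro, pol, env	as printed
I	K134	chr12:55727215-55728183	969	968	7243	In frame pol broken	TGA/pol	as printed
II	K104	chr5:30486760-30496205	951	960	7535	-	TGA/gag, pol, env	as printed
II	K108a	chr7:4622057-4631528	968	968	7535	Dual internal sequences, triple LTRs	TAG/gag, env	as printed
II	K108b	chr7:4630561-4640031	968	968	7535	-	TAG/gag	as printed
II	K109	chr6:78426662-78436083	960	960	7502	-	TAG, TGA/pol	as printed
II	K113	chr19:21841536-21841541	968	968	7536	-	-	as printed
II	K115	chr8:7355397-7364859	960	968	7535	-	-	as printed
II	K118	chr11:101565794-101575259	968	968	7530	-	TGA/gag, env	as printed
II	K119	chr12:58721242-58730698	968	968	7521	-	-	as printed
II	K121	chr3:125609302-125618439	804	804	7530	-	TAG, TGA/gag, pro, pol, env	as printed
II	K132	chr19:28128498-28137384	23	995	7869	Alu insertion within internal/pol broken	-	position corrected from a duplicate of K113's (locus table value used)
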