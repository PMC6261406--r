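location	genes	type	size_kb	sample_id	pop_freq
chr1:196964969-196987806	CFHR5	Del	23	SLE005	-
chr2:34219274-34313413	-	Del	94	SLE009	< 1%
chr2:36932842-36964864	VIT	Del	32	SLE010	-
chr3:65517399-65595008	MAGI1	Dup	78	SLE015	< 1%
chr5:96625630-96865984	-	Del	240	SLE014	-
chr6:152303218-152311895	ESR1	Del	9	SLE003	< 1%
chr7:11983316-12078163	-	Dup	95	SLE005	< 1%
chr7:85522989-85709099	-	Del	186	SLE003	< 1%
chr7:114209440-114215739	FOXP2	Del	6	SLE023	-
chr7:146859536-146868357	CNTNAP2	Del	9	SLE003	-
chr8:30079990-30202711	MIR548O2	Dup	123	SLE018	-
chr9:137354612-137529641	-	Dup	175	SLE023	< 1%
chr12:21796951-22445614	LDHB, KCNJ8, ABCC9, CMAS, ST8SIA1	Dup	649	SLE018	< 1%
chr13:93378273-93386333	GPC5	Del	8	SLE023	-
chr13:94506273-94515199	GPC6, GPC6-AS2	Del	9	SLE023	< 1%
chr13:104521177-104647267	-	Del	126	SLE013	-
chr14:67111441-67148873	GPHN	Dup	37	SLE011	-
chr14:67193022-67217571	GPHN	Del	25	SLE016	< 1%
chr22:25066486-25112325	-	Del	46	SLE006	< 1%
chrX:15723836-15831401	CA5B, INE2, ZRSR2	Dup	108	SLE018	-
chrX:52833688-52904643	XAGE5, XAGE3	Dup	71	SLE017	-
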