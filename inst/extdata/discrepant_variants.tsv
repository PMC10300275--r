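gene	rsid	hgvs_c	consequence	clinvar_raw	cadd	maf_exac_nfe	sanger	gc_pct	depth_detecting	depth_other	platform	reason
PCSK7	rs781628227	c.2347C>G	Exonic non-synonymous	Not_Found	24.5	0	Confirmed	55.9	569	0	TS	Insufficient coverage in WES
CIDEC	rs757906759	c.209C>T	Exonic non-synonymous	Not_Found	32	0.00004496	Confirmed	51.3	436	298	TS	No VQSR filtering pass in WES pipeline
SMPD1	rs78250081	c.113C>T	Exonic non-synonymous	Not_Found	17.7	0.00005943	Not Confirmed	73.5	610	54	TS	False-positive variant calling in TS due to mis-alignment in repetitive region
CP	rs61733458	c.1652C>T	Exonic non-synonymous	Benign	29.7	0.0301	Confirmed	44.8	199	94	TS	No VQSR filtering pass in WES pipeline
RTEL1	rs201365106	c.232G>A	Exonic non-synonymous	Uncertain significance	2.8	0	Not Confirmed	75	498	275	TS	False-positive variant calling in TS due to mis-alignment in CG-rich region
PCSK7	NA	c.1737C>A	Exonic non-synonymous	Not_Found	41	0	Confirmed	60	754	0	TS	Insufficient coverage in WES
CAV1	rs150368249	c.463G>A	Exonic non-synonymous	Likely benign	16.3	0.0002472	Confirmed	46.8	165	15	WES	Insufficient coverage in TS
PHKA2	rs145406549	c.785T>G	Exonic non-synonymous	Not_Found	27.9	0.0003297	Confirmed	40.2	219	14	WES	Insufficient coverage in TS
PHKB	rs151155518	c.500A>G	Exonic non-synonymous	Conflicting interpretations of pathogenicity	27.2	0.006614	Confirmed	44.4	74	10	WES	Insufficient coverage in TS
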