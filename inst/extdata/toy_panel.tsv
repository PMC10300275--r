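gene	category	chrom	start	end	region_type
HFE	iron overload	chr1	10000	10180	exon
HFE	iron overload	chr1	10600	10790	exon
HFE	iron overload	chr1	11400	11550	exon
LDLR	lipid metabolism	chr1	50000	50200	exon
LDLR	lipid metabolism	chr1	50700	50850	exon
LDLR	lipid metabolism	chr1	49800	49950	utr
ABCB4	cholestatic diseases	chr2	20000	20160	exon
ABCB4	cholestatic diseases	chr2	20500	20680	exon
ABCB4	cholestatic diseases	chr2	21100	21240	exon
GBA	storage diseases	chr2	60000	60150	exon
GBA	storage diseases	chr2	60550	60720	exon
SERPINA1	specific hereditary CLD	chr3	30000	30190	exon
SERPINA1	specific hereditary CLD	chr3	30700	30860	exon
SERPINA1	specific hereditary CLD	chr3	29700	29850	promoter
PNPLA3	susceptibility to liver diseases	chr3	70000	70170	exon
PNPLA3	susceptibility to liver diseases	chr3	70600	70760	exon
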