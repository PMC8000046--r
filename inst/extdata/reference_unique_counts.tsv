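# Reference per-substrate unique observation counts (function specificity
# diversity) for species with top-ranking diversity totals.
genome_id	species	genus	class	phylum	cellulose	pectin	xylan	lignin
g_col_g25	Colletotrichum sp. COLG25	Colletotrichum	Sordariomycetes	Ascomycota	17	53	24	18
g_col_tro	Colletotrichum tropicale	Colletotrichum	Sordariomycetes	Ascomycota	16	53	25	18
g_par_ror	Paramyrothecium roridum	Paramyrothecium	Sordariomycetes	Ascomycota	18	49	25	17
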