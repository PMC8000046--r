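# Reference per-substrate redundant observation counts for ten fungal
# species with top-ranking total biomass degrading capacity. Used to
# rebuild genome profiles and verify aggregate arithmetic (totals and
# substrate-association sums).
genome_id	species	genus	class	phylum	cellulose	pectin	xylan	lignin
g_pec_rum	Pecoramyces ruminatium	Pecoramyces	Neocallimastigomycetes	Chytridiomycota	248	85	208	0
g_neo_cal	Neocallimastix californiae	Neocallimastix	Neocallimastigomycetes	Chytridiomycota	232	122	172	0
g_myc_cit	Mycena citricolor	Mycena	Agaricomycetes	Basidiomycota	91	204	50	149
g_ver_lon	Verticillium longisporum	Verticillium	Sordariomycetes	Ascomycota	139	176	74	95
g_con_2t2	Coniochaeta sp. 2T2.1	Coniochaeta	Sordariomycetes	Ascomycota	117	102	108	98
g_par_ror	Paramyrothecium roridum	Paramyrothecium	Sordariomycetes	Ascomycota	106	163	63	79
g_cad_dse	Cadophora sp. DSE1049	Cadophora	Leotiomycetes	Ascomycota	105	138	75	91
g_dia_amp	Diaporthe ampelina	Diaporthe	Sordariomycetes	Ascomycota	116	129	58	97
g_dia_lon	Diaporthe longicolla	Diaporthe	Sordariomycetes	Ascomycota	111	128	56	90
g_dia_njd	Diaporthe sp. NJD1	Diaporthe	Sordariomycetes	Ascomycota	111	118	58	94
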