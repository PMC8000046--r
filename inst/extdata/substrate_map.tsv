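# Default substrate-association map: an illustrative curation of canonical
# cellulase, xylanase, pectin-active and ligninolytic EC functions across
# their usual GH/PL/CE/AA families. Working default for demonstration and
# testing; NOT a comprehensive curation of CAZyme substrate associations.
ec_pattern	family_pattern	substrates
3.2.1.4	*	cellulose
3.2.1.91	*	cellulose
3.2.1.176	*	cellulose
3.2.1.21	*	cellulose
3.2.1.74	*	cellulose
3.2.1.151	*	cellulose
3.2.1.6	*	cellulose
3.2.1.58	*	cellulose
*	GH6	cellulose
*	GH7	cellulose
*	GH45	cellulose
3.2.1.*	GH131	cellulose
1.1.99.18	*	cellulose,lignin
3.2.1.8	*	xylan
3.2.1.37	*	xylan
3.2.1.55	*	xylan
3.2.1.131	*	xylan
3.2.1.139	*	xylan
3.2.1.156	*	xylan
3.1.1.72	*	xylan
3.2.1.72	*	xylan
*	GH11	xylan
3.1.1.73	*	xylan,pectin
3.2.1.15	*	pectin
3.2.1.67	*	pectin
3.2.1.82	*	pectin
3.2.1.89	*	pectin
3.2.1.171	*	pectin
3.2.1.173	*	pectin
3.1.1.11	*	pectin
3.1.1.86	*	pectin
4.2.2.2	*	pectin
4.2.2.10	*	pectin
4.2.2.23	*	pectin
4.2.2.24	*	pectin
*	PL1	pectin
*	PL3	pectin
*	PL4	pectin
1.10.3.2	*	lignin
1.11.1.13	*	lignin
1.11.1.14	*	lignin
1.11.1.16	*	lignin
1.11.1.7	*	lignin
1.1.3.7	*	lignin
*	AA2	lignin
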