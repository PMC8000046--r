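# Reference (redundant, unique) observation-count pairs for Redundancy
# Multiplication Score checks.
label	redundant	unique
pecoramyces_total	208	16
mycena_pectin	204	24
verticillium_total	108	22
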