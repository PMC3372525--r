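# Column counts (millions) and alignment counts from a proteome-scale
# mammalian scan: all columns with a human residue, the selected subset,
# and its fit / conserved partition.
subset	columns_millions	alignments
include_human	7.01	12746
selected	3.64	7708
fit	0.73	7590
conserved	2.91	118
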