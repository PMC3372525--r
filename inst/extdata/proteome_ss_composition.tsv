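# Secondary-structure composition of the human proteome and of the
# longevity-selected positions of a proteome-scale mammalian scan (real and
# trait-randomized control), with the published percentages per class.
subset	helix	strand	coil	total	helix_pct	strand_pct	coil_pct
proteome	2108348	956422	3974432	7039202	29.95	13.59	56.46
real	1922	736	5044	7702	24.95	9.56	65.49
control	160	62	466	688	23.26	9.01	67.73
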