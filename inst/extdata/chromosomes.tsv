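name	length_bp	centromere_bp	locus_bp	locus_name
chrV	577000	152000	116000	URA3
chrII	813000	238000	470000	LYS2
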