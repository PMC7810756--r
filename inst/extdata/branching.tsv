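event_type	products	probability
ionization	H3O+,OH,e_aq-	1
excitation_a1b1	OH,H	0.65
excitation_a1b1		0.35
excitation_b1a1	H3O+,OH,e_aq-	0.55
excitation_b1a1	OH,OH,H2	0.15
excitation_b1a1		0.3
excitation_rydberg	H3O+,OH,e_aq-	0.5
excitation_rydberg		0.5
attachment	OH,OH-,H2	1
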