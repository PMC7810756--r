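reactant1	reactant2	products	k	order
H	H	H2	5030000000	2
H	OH		15500000000	2
H	H2O2	OH	35000000	2
H	e_aq-	H2,OH-	25000000000	2
H	OH-	e_aq-	25100000	2
H	O2	HO2	21000000000	2
H	HO2	H2O2	10000000000	2
H	O2-	HO2-	10000000000	2
OH	OH	H2O2	5500000000	2
OH	H2O2	HO2	28700000	2
OH	H2	H	32800000	2
OH	e_aq-	OH-	29500000000	2
OH	OH-	O-	6300000000	2
OH	HO2	O2	7900000000	2
OH	O2-	OH-,O2	10700000000	2
OH	HO2-	OH-,HO2	8320000000	2
OH	O-	HO2-	1000000000	2
H2O2	e_aq-	OH-,OH	11000000000	2
H2O2	OH-	HO2-	12700000000	2
H2O2	O-	HO2,OH-	555000000	2
e_aq-	e_aq-	OH-,OH-,H2	5000000000	2
e_aq-	H3O+	H	21100000000	2
e_aq-	O2-	H2O2,OH-,OH-	13000000000	2
e_aq-	HO2-	O-,OH-	3510000000	2
e_aq-	O2	O2-	17400000000	2
e_aq-	HO2	HO2-	12800000000	2
H3O+	O2-	HO2	47800000000	2
H3O+	OH-		113000000000	2
H3O+	HO2-	H2O2	50000000000	2
HO2	O2-	O2,HO2-	97000000	2
HO2	HO2	O2,H2O2	830000	2
O-	NA	OH,OH-	1360000	1
HO2-	NA	H2O2,OH-	1360000	1
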