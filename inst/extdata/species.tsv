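species	n_h	n_o	charge	diff_coef	radical	vdw_radius	mass
e_aq-	0	0	-1	4.9	TRUE	NA	NA
OH	1	1	0	2.8	TRUE	NA	NA
H	1	0	0	7	TRUE	NA	NA
H2	2	0	0	4.8	FALSE	NA	NA
H3O+	3	1	1	9.46	FALSE	NA	NA
OH-	1	1	-1	5.3	FALSE	NA	NA
H2O2	2	2	0	2.3	FALSE	NA	NA
O2	0	2	0	2.4	FALSE	NA	NA
O2-	0	2	-1	1.75	TRUE	NA	NA
HO2	1	2	0	2.3	TRUE	NA	NA
HO2-	1	2	-1	1.4	FALSE	NA	NA
O-	0	1	-1	2	TRUE	NA	NA
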