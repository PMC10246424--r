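step1_cancer_antigen_release	synthetic_fixture	BG_0042	BG_0159	BG_0103	BG_0194	BG_0015	BG_0118	BG_0136	BG_0067
step2_antigen_presentation	synthetic_fixture	BG_0168	BG_0022	BG_0175	BG_0136	BG_0059	BG_0090	BG_0012	BG_0179
step3_priming_activation	synthetic_fixture	BG_0148	BG_0040	BG_0031	BG_0134	BG_0144	BG_0150	BG_0187	BG_0021
step4_immune_cell_recruiting	synthetic_fixture	BG_0132	BG_0139	BG_0102	BG_0026	BG_0130	BG_0100	BG_0166	BG_0171
step5_immune_infiltration	synthetic_fixture	BG_0200	BG_0124	BG_0123	BG_0036	BG_0003	BG_0109	BG_0181	BG_0088
step6_cancer_cell_recognition	synthetic_fixture	BG_0041	BG_0181	BG_0022	BG_0008	BG_0173	BG_0200	BG_0031	BG_0034
step7_cancer_cell_killing	synthetic_fixture	BG_0032	BG_0140	BG_0149	BG_0072	BG_0186	BG_0088	BG_0074	BG_0174
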