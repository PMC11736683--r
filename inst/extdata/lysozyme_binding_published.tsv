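cavity	class	tbar_ns	tbar_se_ns	n	t_ns	occupancy_pct	dF_bind_kJ_mol
cavity 1	hydrophilic	0.263	0.023	283	74.56	0.064	5.26
cavity 2	hydrophilic	0.124	0.010	830	103.26	0.089	4.41
cavity 3	hydrophobic	0.542	0.022	1098	595.36	0.513	-0.107
cavity 4	hydrophobic	0.625	0.023	2738	1710.50	1.475	-2.83
cavity 5	random	0.158	0.012	427	67.44	0.058	5.51
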