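# Published per-SD odds ratios for five genetically predicted metabolic
# exposures against endometrial cancer (inverse-variance weighted model,
# 1287 cases / 8273 controls; OR and 95% CI printed to 2 decimals, p as
# printed). p_half_ulp is half a unit in the last printed digit of p.
# Used for round-trip consistency checks via se_from_ci().
exposure	sd_scale	sd_units	n_snps	or_per_sd	ci_low	ci_high	p_printed	p_half_ulp
body_mass_index	4.81	kg/m^2	32	3.86	2.24	6.64	1.2e-6	5e-8
fasting_glucose	0.65	mmol/L	36	1.00	0.67	1.50	0.99	0.005
fasting_insulin	0.60	ln(pmol/L)	18	2.34	1.06	5.14	0.03	0.005
early_insulin_secretion	0.58	ln(pmol/L)	17	1.40	1.12	1.76	0.003	0.0005
type_2_diabetes	1	log-odds	49	0.91	0.79	1.04	0.16	0.005
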