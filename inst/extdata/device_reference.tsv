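configuration	radius_nm	fill_fraction	wavelength_nm	intensity_mW_mm2	jsc_A_m2	voc_V	ff_pct	pce_pct
bare_453	NA	0	453	0.33	9.5	0.67	78.5	1.5
bare_453	NA	0	453	0.26	7.5	0.67	75.5	1.4
bare_250	NA	0	250	0.33	23	0.68	78	3.5
bare_250	NA	0	250	0.26	19	0.68	77.5	3.8
embedded_f5	7.5	0.05	453	0.33	25	0.68	76.5	4
embedded_f5	10	0.05	453	0.26	25	0.68	76.5	5
embedded_f7.5	7.5	0.075	453	0.33	30	0.685	78	4.8
embedded_f7.5	10	0.075	453	0.26	32	0.685	75.2	6.3
embedded_f10	7.5	0.10	453	0.33	35	0.69	76.5	5.6
embedded_f10	10	0.10	453	0.26	38	0.69	80	8
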