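variable	normal	hyper	t39_5	t42	control	low	high
ch4_ml	87.3	49.3	66.7	69.9	50.6	60.1	94.2
co2_ml	423.8	277.7	346.3	355.3	328.0	341.3	383.0
total_gas	550.3	365.5	450.6	465.2	418.6	438.2	516.9
ch4_pct	15.6	12.8	14.1	14.3	11.6	13.2	17.8
co2_pct	77.2	76.0	76.9	76.3	77.8	77.9	74.1
ch4_per_g_om	13.5	7.9	10.7	10.7	7.8	9.5	14.8
ch4_per_g_dm	12.2	7.1	9.7	9.7	7.0	8.6	13.4
mcr	1.63	0.92	1.24	1.30	0.94	1.12	1.75
h2_acetate	59.9	50.3	53.9	56.3	52.0	55.5	57.8
h2_butyrate	20.8	21.3	21.1	20.9	20.5	21.1	21.5
h2_caproate_produced	3.76	2.99	3.02	3.74	3.60	3.37	3.17
h2_propionate	16.4	16.7	17.6	15.5	15.7	16.8	17.0
h2_valerate	3.23	2.75	2.77	3.20	3.01	3.01	2.94
h2_caproate_utilized	7.5	6.0	6.0	7.5	7.2	6.7	6.3
h2_ch4	13.8	7.8	10.5	11.1	8.0	9.5	14.9
production_p1	80.6	71.6	75.0	77.2	72.4	76.6	79.3
utilization_p1	40.9	33.2	36.9	37.2	33.9	36.1	41.2
gain_p1	39.7	38.4	38.1	40.0	38.5	40.5	38.1
recovery_p1	51.2	47.2	49.7	48.7	47.4	47.7	52.4
production_p2	84.4	74.6	78.0	80.9	76.0	79.9	82.4
utilization_p2	33.4	27.2	30.9	29.7	26.7	29.4	34.8
gain_p2	51.0	47.4	47.1	51.1	49.3	50.6	47.6
recovery_p2	39.9	36.8	39.8	36.9	35.3	37.2	42.5
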