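pigment	rt_center	rt_min	rt_max	response_factor
neo	2.6	2.1	3.1	0.01
vio	3.6	3.1	4.1	0.012
ant	4.6	4.1	5.1	0.011
lut	5.6	5.1	6.1	0.009
zea	6.6	6.1	7.1	0.013
chl_b	8.6	8	9.2	0.008
chl_a	10.2	9.6	10.8	0.007
beta_car	13	12.4	13.6	0.012
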