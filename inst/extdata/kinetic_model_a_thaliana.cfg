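# xanthoq kinetic model configuration
species_label = A. thaliana
k_de1 = 0.049928871225896489
k_de2 = 0.049928871225896489
k_ep = 0.02
dtt_inhibition = 0
vivo_rate_scale = 4
ph_opt = 5.0999999999999996
slope_acid = 3
slope_alkaline = 2
ph_offset = 0.80000000000000004
ph_dark = 7
ph_min = 5
light_k_half = 500
ph_tau = 30
q_qe_max = 1.6000000000000001
q_qz_max = 1
q_qi_max = 0.45000000000000001
q_k_qe_ind = 0.033333333333333333
q_k_qe_rel = 0.016666666666666666
q_ph_qe = 6
q_s_qe = 0.14999999999999999
q_kz_frac = 0.040000000000000001
q_k_qz = 0.0033333333333333335
q_k_qi_ind = 0.0016666666666666668
q_k_qi_rel = 0.00013888888888888889
q_i_half_qi = 700
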