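{"V_B":0.169021,"V_P":0.1075418,"V_R":0.1225871,"V_O":0.0277367,"V_C":0.1868556,"V_K":0.2,"a_B":0.2817017,"a_P":0.3021655,"a_R":0.8814709,"a_O":0.0779332,"a_C":0.3021655,"a_K":0.2,"g1":4,"g2":1,"g3":1.5,"g4":1.4479602,"g5":2.5652409,"f_P":7.8946898,"k_P":0.7055468,"f_R":24.5845118,"k_R":0.7055468,"f_O":7.8946898,"k_O":0.7055468,"f_C":7.8946898,"k_C":0.7055468,"h_a":3,"k_I":1,"h_I":9.8341661,"k_RC":1.4479602,"h_RC":1.5,"p_K":0.5195667,"p_B":0.7229719,"k_ass":0.6323229,"d_KC":0.4068104,"d_BC":0.4068104,"d_CB":0.3161615,"q_P":0.2224623,"q_C":0.2224623,"d_PER":0.0558704,"d_CRY":0.0558704,"k_pc":0.1665919,"d_PCc":0.0333184,"k_tPC":0.1332735,"d_PC":0.1409707,"p_REV":0.9334274,"d_REV":0.9334274,"p_ROR":0.0641331,"d_ROR":0.0641331,"obs_scale":1}
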