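silver:
  eps_inf: 3.7
  hw_p_eV: 9.01
  gamma_eV: 0.511352281218264
blend:
  cauchy_A: 1.695718214634006
  cauchy_B_nm2: 40000.0
  uv_center_nm: 250.0
  uv_width_nm: 120.0
  vis_center_nm: 500.0
  vis_width_nm: 180.0
  k_uv: 0.139348091530355
  k_vis: 0.053652515870407
attenuation:
  layer_path_nm: 377.160755496116337
  kappa_np: 0.440082430760929
photocurrent:
  k_c_abs_nm2: 1500.0
  l_influence_nm: 25.0
  kappa_A: 0.220133283688557
  kappa_K: 0.120227940016388
electrode:
  z_interface_ohm_m2: 0.0043
  j_threshold_A_m2: 25.100000000000001
anchors:
  jsc_bare_453_A_m2: 7.5
  jsc_bare_250_A_m2: 19.0
  q_abs_peak_r10: 2.4
  t_np_f10: 0.946
  t_layer_f075: 0.57
  jsc_r5_f5_withK_A_m2: 15.0
  jsc_r75_f10_withK_033: 36.0
  jsc_r75_f10_noK_033: 33.0
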