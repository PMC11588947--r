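n_straight: 33.0
n_lesbian: 25.0
seed: 1.0
base_log_latency: 7.313220387090301
participant_sd: 0.2
residual_log_sd: 0.45
irap_effect_matrix:
  straight:
    '1': 0.1875
    '2': 0.1313
    '3': -0.0609
    '4': -0.0703
  lesbian:
    '1': -0.0208
    '2': 0.2031
    '3': 0.4062
    '4': 0.3021
irap_effect_sd:
  straight: 0.127
  lesbian: 0.174
long_latency_rate: 0.01
fast_responder_rate: 0.0
practice_fail_rate: 0.557
fast_p0: 0.35
fast_p_inf: 0.95
fast_learn_rate:
  straight_block:
    straight: 0.0153
    lesbian: 0.0053
  lesbian_block:
    straight: 0.0132
    lesbian: 0.0269
fast_kappa_sd: 0.65
fast_timeout_rate: 0.02
ksog_group_means:
  straight: 1.2
  lesbian: 4.32
ksog_group_sds:
  straight: 0.8
  lesbian: 0.56
ksog_cell_sd: 0.5
ksog_missing_lesbian: 4.0
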