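# Default monthly hazard profiles for the four clinic-molecular risk groups.
# Each recurrence endpoint gets a log-normal-shaped monthly hazard bump:
#   h_e[m] = k_g * weight_e * dlnorm(m, log(median_e), sdlog_e),  m = 1..60
# median_e are the observed median event times (months from end of treatment);
# mode_e place the hazard peaks (sdlog_e = sqrt(log(median_e / mode_e))).
# The per-group scale k_g is solved at load time so that the composite
# disease-failure (DM/LR/RR/death) cumulative incidence at month 60 equals
# df_target_5yr exactly in the hazard model.
version: 1
horizon_months: 60
death_hazard_monthly: 0.0005     # background death without recurrence
censor_hazard_monthly: 0.003     # loss to follow-up before month 60
endpoints:
  DM: {median: 18.7, mode: 12.0, weight: 13.3}
  LR: {median: 27.9, mode: 19.0, weight: 6.7}
  RR: {median: 25.0, mode: 19.0, weight: 5.6}
df_target_5yr:
  I: 0.054
  II: 0.186
  III: 0.343
  IV: 0.414
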