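# SYNTHETIC baseline parameters for the Markov cohort model.
# The study that motivated this package drew its baseline clinical estimates,
# utilities and 2019 Guangzhou payer costs from a supplement that is not
# publicly available; the values below are plausible placeholders in the
# right clinical ranges, NOT the study's values. Absolute costs/QALYs computed
# with them are illustrative; incremental ICER arithmetic is parameter-free.
label: synthetic-baseline-v1
states: [NED, early_recurrence, advanced_recurrence, salvage_treatment, NED_after_salvage, death]
utilities:            # QALY weight per year in each state
  NED: 0.90
  early_recurrence: 0.75
  advanced_recurrence: 0.50
  salvage_treatment: 0.60
  NED_after_salvage: 0.85
  death: 0.0
costs_monthly:        # $ per cycle of state occupancy
  NED: 0
  early_recurrence: 400
  advanced_recurrence: 900
  salvage_treatment: 2500
  NED_after_salvage: 10
  death: 0
visit_cost: 120       # $ per surveillance visit, charged to at-risk occupancy
transitions:          # per-cycle probabilities
  ned_death: 0.0005         # background death without recurrence
  er_to_salvage: 0.90
  er_death: 0.005
  ar_to_salvage: 0.70
  ar_death: 0.040
  salvage_to_ned: 0.12
  salvage_death: 0.015
  neds_death: 0.003
tail_hazard_monthly: 0.0005 # recurrence onset hazard beyond month 60
early_window_months: 3      # detection within this delay counts as early-stage
discount_annual: 0.0
horizon_cycles: 480         # 40 years of monthly cycles
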