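# Base-case parameter set: watch-and-wait versus low anterior resection.
# Probabilities and utilities carry beta uncertainty distributions, costs gamma
# (2019 US$, payer perspective). A missing sd is filled as 0.20 * mean at load.
comparison: WW_vs_LAR
timeline:
  cycle_length_months: 1
  horizon_cycles: 60
  annual_discount_rate: 0.03
  postop_recovery_cycles: 2
  adjuvant_chemo_duration_cycles: 4
  adjuvant_chemo_start_offset_cycles: 2   # months post-resection; 1/2/3 = 4/8/12 weeks
  lar_ostomy_duration_cycles: 6
  wtp_threshold: 100000
  cohort_size: 10000
  psa_outer_iterations: 100
  baseline_age_years: 65
  ww_adjuvant_chemo: yes
  local_interpolation: row_horizon
transitions:
  perioperative_death: {mean: 0.035, sd: 0.007, source: "Marijnen 2002"}
  local_recurrence_2y:
    WW:  {mean: 0.19, sd: 0.04, source: "Dossa 2017"}
    TME: {mean: 0.016, sd: 0.003, source: "Dossa 2017"}
  local_recurrence_5y:
    WW:  {mean: 0.24, sd: 0.05, source: "van der Valk 2018; Smith 2019"}
    TME: {mean: 0.010, sd: 0.002, source: "Miller 2020"}
  salvage_given_local:
    WW:  {mean: 0.94, sd: 0.19, source: "Dossa 2017"}
    TME: {mean: 0.59, sd: 0.12, source: "Ikoma 2017"}
  distant_recurrence_5y:
    WW:  {mean: 0.10, sd: 0.02, source: "Dossa 2017"}
    TME: {mean: 0.079, sd: 0.016, source: "Dossa 2017"}
  concurrent_distant_given_local: {mean: 0.056, sd: 0.011, source: "van der Valk 2018"}
  concurrent_local_given_distant: {mean: 0.17, sd: 0.034, source: "van der Valk 2018"}
  distant_after_local_3y: {mean: 0.11, sd: 0.023, source: "van der Valk 2018"}
  mortality_local_salvaged_5y: {mean: 0.50, sd: 0.10, source: "Rao 2017"}
  mortality_local_unsalvaged_5y: {mean: 0.70, sd: 0.14, source: "Rao 2017"}
  mortality_distant_5y: {mean: 0.80, sd: 0.16, source: "Rao 2017"}
  mortality_local_and_distant_5y: {mean: 0.80, sd: 0.16, source: "Rao 2017"}
utilities:
  initial_ww: {mean: 0.80, sd: 0.16, source: "Couwenberg 2018"}
  initial_postop: {mean: 0.110, sd: 0.022, source: "van den Brink 2004"}
  salvage_tme_disutility_state: {mean: 0.69, sd: 0.14, source: "van den Brink 2004"}
  longterm_lar_with_ostomy: {mean: 0.70, sd: 0.14, source: "Couwenberg 2018"}
  longterm_lar_without_ostomy: {mean: 0.78, sd: 0.16, source: "Couwenberg 2018"}
  local_recurrence: {mean: 0.67, sd: 0.13, source: "van den Brink 2004"}
  distant_recurrence: {mean: 0.70, sd: 0.14, source: "van den Brink 2004"}
  local_and_distant: {mean: 0.48, sd: 0.096, source: "van den Brink 2004"}
  death: {mean: 0.0, family: fixed}
costs:
  surgery_lar: {mean: 34662.98, sd: 6932.60, source: "Raldow 2019"}
  adjuvant_chemo_per_cycle: {mean: 1890.00, sd: 378.00, source: "Raldow 2019"}
  ostomy_takedown: {mean: 906.02, sd: 181.20, source: "2019 Physician's Fee Schedule"}
  ostomy_care_monthly: {mean: 93.25, sd: 18.65, source: "2020 DMEPOS Schedule"}
  office_visit: {mean: 25.95, sd: 5.19, source: "2019 Physician's Fee Schedule"}
  rectal_exam: {mean: 9.01, sd: 1.80, source: "2019 Physician's Fee Schedule"}
  flex_sig: {mean: 58.74, sd: 11.75, source: "2019 Physician's Fee Schedule"}
  cea_test: {mean: 23.41, sd: 4.68, source: "2019 Physician's Fee Schedule"}
  colonoscopy: {mean: 194.97, sd: 38.99, source: "2019 Physician's Fee Schedule"}
  ct_abd_pelvis: {mean: 323.99, sd: 64.80, source: "2019 Physician's Fee Schedule"}
  ct_chest: {mean: 161.09, sd: 32.22, source: "2019 Physician's Fee Schedule"}
  mri_pelvis: {mean: 405.08, sd: 81.02, source: "2019 Physician's Fee Schedule"}
  restaging_local: {mean: 2100.00, sd: 420.00, source: "Miller 2020"}
  restaging_distant: {mean: 1200.00, sd: 240.00, source: "Miller 2020"}
  reirradiation_course: {mean: 19800.00, sd: 3960.00, source: "Miller 2020"}
  palliative_capecitabine_per_cycle: {mean: 510.00, sd: 102.00, source: "Miller 2020"}
  palliative_mfolfox6_per_cycle: {mean: 850.00, sd: 170.00, source: "Miller 2020"}
  death_perioperative: {mean: 11295.38, sd: 2259.08, source: "Duncan 2019"}
  death_cancer: {mean: 11295.38, sd: 2259.08, source: "Duncan 2019"}
  death_noncancer: {mean: 11295.38, sd: 2259.08, source: "Duncan 2019"}
surveillance:
  # cycles (months since entering the disease-free state) at which each
  # surveillance cost item is billed
  WW:
    office_visit: [3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54, 60]
    rectal_exam:  [3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54, 60]
    flex_sig:     [3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54, 60]
    cea_test:     [3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54, 60]
    ct_abd_pelvis: [12, 24, 36, 48, 60]
    ct_chest:      [12, 24, 36, 48, 60]
    mri_pelvis:    [6, 12, 18, 24, 36, 48, 60]
    colonoscopy:   [12]
  postop:
    office_visit: [3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54, 60]
    cea_test:     [3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54, 60]
    ct_abd_pelvis: [12, 24, 36, 48, 60]
    ct_chest:      [12, 24, 36, 48, 60]
    colonoscopy:   [12]
life_table: life_table_2015_synthetic.tsv
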