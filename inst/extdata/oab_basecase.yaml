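# Base-case parameter set for the overactive-bladder antimuscarinic
# cost-effectiveness model. Efficacy/persistence values are percentages with
# the two-decimal precision of the source tables; they are converted to
# fractions when loaded. Costs are 2010 euros.
#
# Solifenacin efficacy is the placebo row scaled by the published relative
# risks (1.50 for 5 mg, 1.53 for 10 mg); the week-12|week-8 responder
# conditional is taken equal to placebo. The values below are the printed
# (derived) cells.

arms:
  placebo:
    start_dose: "placebo"
    doses:
      placebo:
        response_w2_pct: 20.99
        response_w8_pct: 34.66
        response_w12_pct: 27.84
        cond_w12_given_w8resp_pct: 80.33
        cond_w12_given_w8nonresp_pct: 14.16
        nocturia_resolution_w12_pct: 54.34
        constipation_rate_pct: 1.99
  fesoterodine:
    start_dose: "4mg"
    high_dose: "8mg"
    doses:
      4mg:
        response_w2_pct: 30.41
        response_w8_pct: 50.00
        response_w12_pct: 43.67
        cond_w12_given_w8resp_pct: 87.34
        cond_w12_given_w8nonresp_pct: 21.05
        nocturia_resolution_w12_pct: 55.56
        constipation_rate_pct: 4.15
      8mg:
        response_w2_pct: 40.59
        response_w8_pct: 55.38
        response_w12_pct: 50.21
        cond_w12_given_w8resp_pct: 90.65
        cond_w12_given_w8nonresp_pct: 24.20
        nocturia_resolution_w12_pct: 55.90
        constipation_rate_pct: 6.01
  tolterodine:
    start_dose: "4mg"
    doses:
      4mg:
        response_w2_pct: 29.23
        response_w8_pct: 49.47
        response_w12_pct: 38.18
        cond_w12_given_w8resp_pct: 77.17
        cond_w12_given_w8nonresp_pct: 13.04
        nocturia_resolution_w12_pct: 57.69
        constipation_rate_pct: 2.76
  solifenacin:
    start_dose: "5mg"
    high_dose: "10mg"
    doses:
      5mg:
        response_w2_pct: 31.49
        response_w8_pct: 51.99
        response_w12_pct: 41.76
        cond_w12_given_w8resp_pct: 80.33
        cond_w12_given_w8nonresp_pct: 21.24
        nocturia_resolution_w12_pct: 54.34
        constipation_rate_pct: 3.53
      10mg:
        response_w2_pct: 32.11
        response_w8_pct: 53.01
        response_w12_pct: 42.58
        cond_w12_given_w8resp_pct: 80.33
        cond_w12_given_w8nonresp_pct: 21.66
        nocturia_resolution_w12_pct: 88.72
        constipation_rate_pct: 7.72

# Fraction of starters titrating to the higher dose at the week-4 decision
# point (week-8 trial data used as proxy). Single-dose arms titrate nobody.
titration:
  placebo: {frac_responders_titrate: 0.0, frac_nonresponders_titrate: 0.0}
  fesoterodine: {frac_responders_titrate: 0.5, frac_nonresponders_titrate: 0.5}
  tolterodine: {frac_responders_titrate: 0.0, frac_nonresponders_titrate: 0.0}
  solifenacin: {frac_responders_titrate: 0.5, frac_nonresponders_titrate: 0.5}

# Fraction of starters still on therapy. From week 12 onward all arms follow
# the placebo curve; arm-specific week-8 values are retained for the week-8
# checkpoint.
persistence:
  shared_pct: {2: 100.0, 8: 92.84, 12: 90.64, 24: 79.32, 52: 59.27}
  week8_by_arm_pct:
    placebo: 92.84
    fesoterodine: 92.67
    tolterodine: 95.76
    solifenacin: 94.06

unit_costs:
  pad: 0.58
  gp_visit: 26.78
  specialist_visit: 58.60
  lab_test: 2.56
  constipation_per_day: 0.16
  fracture_event: 5742.8
  skin_infection_episode: 53.1
  uti_episode: 53.1
  depression_per_patient_year: 2699.0
  nursing_home: 14831.4
  drug_per_day:
    fesoterodine: {4mg: 1.70, 8mg: 2.72}
    tolterodine: {4mg: 1.70}
    solifenacin: {5mg: 1.67, 10mg: 2.67}

# Utilization by treatment/continence status.
resource_use:
  controlled:
    frac_using_pads: 0.0
    pads_per_day: 0.0
    gp_visits_per_month: 0.133
    specialist_visits_per_month: 0.117
    lab_tests_per_month: 0.033
  uncontrolled_on_rx:
    frac_using_pads: 0.67
    pads_per_day: 4.23
    gp_visits_per_month: 0.2
    specialist_visits_per_month: 0.15
    lab_tests_per_month: 0.078
  untreated:
    frac_using_pads: 0.67
    pads_per_day: 4.23
    gp_visits_per_month: 0.2
    specialist_visits_per_month: 0.15
    lab_tests_per_month: 0.078

# Comorbidity incidence by status. Fracture/skin/UTI figures are 6-month
# windows (annualized x2 by default, configurable below); depression is an
# annual probability; nursing-home admissions are per 1000 patient-years.
# The untreated column of the source shares the uncontrolled event counts.
comorbidity:
  controlled:
    fracture_prob_6mo: 0.025
    skin_prob_6mo: 0.107
    skin_events_per_person: 0.3
    uti_prob_6mo: 0.19
    uti_events_per_person: 0.3
    depression_prob_annual: 0.0808
    nursing_home_admissions_per_1000py: 29.5
  uncontrolled_on_rx:
    fracture_prob_6mo: 0.053
    skin_prob_6mo: 0.093
    skin_events_per_person: 0.6
    uti_prob_6mo: 0.307
    uti_events_per_person: 0.7
    depression_prob_annual: 0.1884
    nursing_home_admissions_per_1000py: 78.3
  untreated:
    fracture_prob_6mo: 0.053
    skin_prob_6mo: 0.093
    skin_events_per_person: 0.6
    uti_prob_6mo: 0.307
    uti_events_per_person: 0.7
    depression_prob_annual: 0.1884
    nursing_home_admissions_per_1000py: 78.3
  depression_by_sex:
    frac_female: 0.8087
    women: {controlled: 0.091, uncontrolled_on_rx: 0.189}
    men: {controlled: 0.043, uncontrolled_on_rx: 0.186}
  # Relative utility decrements while a comorbidity is present. No value is
  # published for nursing home; it defaults to 0 and is configurable.
  utility_decrements:
    fracture: 0.04
    depression: 0.48
    nursing_home: 0.0

utilities:
  u_continent: 0.9569
  u_incontinent_on_rx: 0.9412
  u_untreated: 0.9332

productivity:
  wage_per_hour: 13.51
  hours_per_week: 40
  frac_employed: 0.5983
  incontinence_hours_reduction: 0.211
  nocturia_impairment: 0.092
  baseline_nocturia_prevalence: 0.4858

conventions:
  horizon_weeks: 52
  perspective: societal
  annualize_six_month: true
  decrements_enabled: false
  wtp_per_qaly: 30000
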