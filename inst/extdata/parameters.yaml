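# Model inputs for the adjuvant-imatinib GIST cost-utility model.
#
# Each parameter carries the reported mean and standard error, the
# distribution family used for probabilistic sensitivity analysis, a role
# (which drives range validation), and an optional time band. se: 0 together
# with family: fixed marks an input that is held constant in the PSA.
#
# Monthly transition probabilities for patients off adjuvant therapy are
# year-banded: the value reported "at year k" is held constant until the
# next reported year (see the recurrence/death band labels below).
#
# The three recurrence-state monitoring costs were reported as concatenated
# digit strings whose split into (mean, se) is ambiguous. Two parses are
# carried: the shipped default is the larger-mean parse
#   cost_rec_imatinib  (4213, 8)   alternative (421, 38)
#   cost_rec_sunitinib (7141, 50)  alternative (714, 150)
#   cost_rec_bsc       (4247, 8)   alternative (424, 78)
# Select the alternative with load_parameters(cost_parse = "small").
# Lifetime results differ by well under 1% either way; drug costs dominate.

scalars:
  annual_discount_rate: 0.03      # per year, applied as (1+r)^(-t/12)
  start_age: 60                   # years at model entry
  cycle_length_months: 1
  wtp: 160000                     # THB per QALY, Thai decision threshold
  horizon_cycles: 480             # 40 years; residual alive mass reported
  include_background_mortality: true

parameters:
  # --- monthly probability of recurrence, no adjuvant therapy (chart review)
  p_rec_yr1:         {mean: 0.0205, se: 0.0041, family: beta, role: probability, band: "months 1-12"}
  p_rec_yr3:         {mean: 0.0154, se: 0.0031, family: beta, role: probability, band: "months 13-36"}
  p_rec_yr5:         {mean: 0.0056, se: 0.0011, family: beta, role: probability, band: "months 37+"}

  # --- monthly probability of GIST death, no recurrence (chart review)
  p_death_gist_yr1:  {mean: 0.0017, se: 0.0003, family: beta, role: probability, band: "months 1-12"}
  p_death_gist_yr3:  {mean: 0.0031, se: 0.0006, family: beta, role: probability, band: "months 13-36"}
  p_death_gist_yr5:  {mean: 0.0028, se: 0.0006, family: beta, role: probability, band: "months 37-60"}
  p_death_gist_yr7:  {mean: 0.0020, se: 0.0004, family: beta, role: probability, band: "months 61-84"}
  p_death_gist_yr9:  {mean: 0.0038, se: 0.0008, family: beta, role: probability, band: "months 85+"}

  # --- hazard ratio of recurrence on adjuvant imatinib vs none
  #     (1-year: trial subgroup; 3-year: Bucher indirect comparison)
  hr_adjuvant_1yr:   {mean: 0.29,  se: 0.0995, family: lognormal, role: hazard_ratio}
  hr_adjuvant_3yr:   {mean: 0.133, se: 0.0543, family: lognormal, role: hazard_ratio}

  # --- monthly probabilities after recurrence, by treatment line
  p_prog_imatinib:   {mean: 0.015,  se: 0.0038, family: beta, role: probability}
  p_prog_sunitinib:  {mean: 0.012,  se: 0.0010, family: beta, role: probability}
  p_death_imatinib:  {mean: 0.0056, se: 0.0009, family: beta, role: probability}
  p_death_sunitinib: {mean: 0.0289, se: 0.0087, family: beta, role: probability}
  p_death_bsc:       {mean: 0.0680, se: 0.0093, family: beta, role: probability}

  # --- monthly probability of discontinuing adjuvant imatinib
  p_disc_1yr_m1_6:   {mean: 0.0136, se: 0.0014, family: beta, role: probability, band: "months 1-6"}
  p_disc_1yr_m7_12:  {mean: 0.0009, se: 0.0001, family: beta, role: probability, band: "months 7-12"}
  p_disc_3yr_m1_6:   {mean: 0.0097, se: 0.0001, family: beta, role: probability, band: "months 1-6"}
  p_disc_3yr_m7_36:  {mean: 0.0028, se: 0.0003, family: beta, role: probability, band: "months 7-36"}

  # --- drug unit prices (DMSIC reference prices, 2014 THB)
  imatinib_tablet_price:    {mean: 3659.40, se: 0, family: fixed, role: cost_per_unit}
  sunitinib_capsule_price:  {mean: 1100.53, se: 0, family: fixed, role: cost_per_unit}

  # --- monthly drug acquisition costs as used in the model
  #     (sunitinib embeds the 4-weeks-on / 2-weeks-off schedule)
  cost_drug_imatinib_month:  {mean: 111306, se: 0, family: fixed, role: cost_per_month}
  cost_drug_sunitinib_month: {mean: 82173,  se: 0, family: fixed, role: cost_per_month}

  # --- monthly monitoring / care costs, excluding drug acquisition
  cost_norec_noadj:  {mean: 2758, se: 308, family: gamma, role: cost_per_month}
  cost_norec_adj:    {mean: 1477, se: 573, family: gamma, role: cost_per_month}
  cost_rec_imatinib: {mean: 4213, se: 8,   family: gamma, role: cost_per_month}
  cost_rec_sunitinib: {mean: 7141, se: 50, family: gamma, role: cost_per_month}
  cost_rec_bsc:      {mean: 4247, se: 8,   family: gamma, role: cost_per_month}
  cost_ae_adjuvant:  {mean: 570,  se: 114, family: gamma, role: cost_per_month}

  # --- direct non-medical costs per hospital visit
  cost_travel_visit:    {mean: 296, se: 24, family: gamma, role: cost_per_visit}
  cost_food_visit:      {mean: 109, se: 11, family: gamma, role: cost_per_visit}
  cost_caregiver_visit: {mean: 99,  se: 37, family: gamma, role: cost_per_visit}

  # --- hospital visits per month by state
  visits_norec_noadj: {mean: 0.3, se: 0.1, family: gamma, role: visits_per_month}
  visits_norec_adj:   {mean: 0.6, se: 0.2, family: gamma, role: visits_per_month}
  visits_rec:         {mean: 1,   se: 0,   family: fixed, role: visits_per_month}

  # --- utilities (EQ-5D-3L, Thai tariff)
  u_norec_noadj:   {mean: 0.89, se: 0.03, family: beta, role: utility}
  u_norec_adj:     {mean: 0.79, se: 0.09, family: beta, role: utility}
  u_rec_imatinib:  {mean: 0.66, se: 0.05, family: beta, role: utility}
  u_rec_sunitinib: {mean: 0.58, se: 0.06, family: beta, role: utility}
  u_rec_bsc:       {mean: 0.42, se: 0.03, family: beta, role: utility}

alternative_parses:
  small:
    cost_rec_imatinib:  {mean: 421, se: 38}
    cost_rec_sunitinib: {mean: 714, se: 150}
    cost_rec_bsc:       {mean: 424, se: 78}
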