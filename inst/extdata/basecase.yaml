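# Base-case model configuration: second-line metastatic gastric cancer.
# Costs are USD per monthly cycle unless marked one-time; probabilities are
# per monthly cycle; month labels count from 0 at treatment start, so month m
# is simulated by cycle m+1 ("0-1" -> cycles 1-2, "2-9" -> 3-10, "10+" -> 11+).

cohort:
  start_age: 60
  male_fraction: 0.70
  msi_h_prevalence: 0.10
  pdl1_pos_prevalence: 0.40
  horizon: 60
  cycle_length_months: 1

economics:
  annual_discount: 0.03
  wtp: 100000
  followup_cost:
    gp: 179.39
    oncology: 355.35
    radiology: 284.00
  bsc_cost_pd: 5169.60
  utility_pf: 0.622
  utility_pd: 0.362
  p_cancer_death_pd: 0.1476
  p_hospitalization: 0.0440
  hospitalization_mode: grade34   # grade34 | claims
  ae_window: 6

biomarker_tests:
  msi: 348.56
  pdl1: 118.51

arms:
  best_supportive_care:
    label: "BSC"
    pf_cost_from_bsc: true
    drug_cost: 0.0
    admin_cost: 0.0
    p_cancer_death: 0.129
    progression:
      - {months: "0-3", p: 0.414}
      - {months: "4-10", p: 0.347}
      - {months: "11+", p: 0.251}
    adverse_events: ~
  paclitaxel:
    label: "PAC"
    drug_cost: 66.53
    admin_cost: 1412.0
    p_cancer_death: 0.028
    progression:
      - {months: "0-3", p: 0.1870}
      - {months: "4-10", p: 0.1730}
      - {months: "11+", p: 0.1430}
    adverse_events:
      p_grade12: 0.0864
      p_grade34: 0.0644
      p_discontinuation: 0.0085
      p_death: 0.0021
      cost_grade34: 13198.0
      disutility_grade12: 0.071
      disutility_grade34: 0.180
  ramucirumab_paclitaxel:
    label: "RAM/PAC"
    drug_cost: 12974.0
    admin_cost: 2118.0
    p_cancer_death: 0.01235
    progression:
      - {months: "0-1", p: 0.1176}
      - {months: "2-11", p: 0.1843}
      - {months: "12+", p: 0.03297}
    adverse_events:
      p_grade12: 0.0306
      p_grade34: 0.1773
      p_discontinuation: 0.0210
      p_death: 0.0034
      cost_grade34: 20658.0
      disutility_grade12: 0.110
      disutility_grade34: 0.250
  pembrolizumab:
    label: "PEM"
    drug_cost: 12246.75
    admin_cost: 470.0
    adverse_events:
      p_grade12: 0.1035
      p_grade34: 0.0237
      p_discontinuation: 0.0028
      p_death: 0.00098
      cost_grade34: 19487.0
      disutility_grade12: 0.086
      disutility_grade34: 0.165
    subgroups:
      biomarker_agnostic:
        p_cancer_death: 0.01857
        progression:
          - {months: "0-1", p: 0.31}
          - {months: "2-9", p: 0.122}
          - {months: "10+", p: 0.014}
      pdl1_positive:
        p_cancer_death: 0.01179
        progression:
          - {months: "0-3", p: 0.2940}
          - {months: "4-10", p: 0.0998}
          - {months: "11+", p: 0.0127}
      msi_high:
        p_cancer_death: 0.0057
        progression:
          - {months: "0-3", p: 0.0835}
          - {months: "4-10", p: 0.0249}
          - {months: "11+", p: 0.0134}

strategies:
  - {id: bsc_all,        name: "BSC, all",                      kind: uniform, arm: bsc}
  - {id: pac_all,        name: "PAC, all",                      kind: uniform, arm: pac}
  - {id: pem_all,        name: "PEM, all",                      kind: uniform, arm: pem_agnostic}
  - {id: ram_pac_all,    name: "RAM/PAC, all",                  kind: uniform, arm: ram_pac}
  - {id: pdl1_pem_pac,   name: "PDL1+: PEM / PDL1-: PAC",       kind: biomarker_split,
     biomarker: pdl1, positive_arm: pem_pdl1, negative_arm: pac}
  - {id: msi_pem_pac,    name: "MSI-H: PEM / MSS: PAC",         kind: biomarker_split,
     biomarker: msi, positive_arm: pem_msi, negative_arm: pac}
  - {id: pdl1_pem_rampac, name: "PDL1+: PEM / PDL1-: RAM/PAC",  kind: biomarker_split,
     biomarker: pdl1, positive_arm: pem_pdl1, negative_arm: ram_pac}
  - {id: msi_pem_rampac, name: "MSI-H: PEM / MSS: RAM/PAC",     kind: biomarker_split,
     biomarker: msi, positive_arm: pem_msi, negative_arm: ram_pac}

# One-way ranges and probabilistic distributions. "pct: 30" means a +/-30%
# multiplicative band on the base value; absolute entries give printed bounds.
sensitivity:
  - {id: msi_h_prevalence, label: "Proportion MSI-H",
     type: absolute, low: 0.02, high: 0.22, sd: 0.05, distribution: beta}
  - {id: prog_pem_msi, label: "Probability of disease progression (MSI-H: PEM)",
     type: multiplier, pct: 30, distribution: uniform, applies: [pem_msi]}
  - {id: prog_other, label: "Probability of disease progression (all other strategies)",
     type: multiplier, pct: 30, distribution: normal, psa_independent: true,
     applies: [bsc, pac, ram_pac, pem_agnostic, pem_pdl1]}
  - {id: p_cancer_death_pd, label: "Probability of cancer mortality on 3L best supportive care",
     type: multiplier, pct: 30, distribution: normal}
  - {id: cost_pem, label: "Total monthly cost: pembrolizumab",
     type: absolute, low: 10831, high: 15331, sd: 1354, distribution: gamma}
  - {id: cost_ae_pem, label: "Cost: pembrolizumab trAEs (grade 3/4)",
     type: absolute, low: 14615, high: 24358, sd: 2436, distribution: gamma}
  - {id: cost_pac, label: "Total monthly cost: paclitaxel",
     type: absolute, low: 1843, high: 2343, sd: 230, distribution: gamma}
  - {id: cost_ae_pac, label: "Cost: paclitaxel trAEs (grade 3/4)",
     type: absolute, low: 9898, high: 16497, sd: 1649, distribution: gamma}
  - {id: cost_ram_pac, label: "Total monthly cost: ramucirumab + paclitaxel",
     type: absolute, low: 11996, high: 16996, sd: 1500, distribution: gamma}
  - {id: cost_ae_ram_pac, label: "Cost: ramucirumab + paclitaxel trAEs (grade 3/4)",
     type: absolute, low: 15493, high: 25822, sd: 2582, distribution: gamma}
  - {id: cost_bsc, label: "Monthly cost: best supportive care",
     type: absolute, low: 4136, high: 6136, sd: 311, distribution: gamma}
  - {id: utility_pf, label: "Utility: 2L progression-free survival",
     type: absolute, low: 0.55, high: 0.69, distribution: uniform}
  - {id: utility_pd, label: "Utility: 3L best supportive care following progression",
     type: absolute, low: 0.22, high: 0.57, distribution: uniform}
  - {id: du12_pem, label: "Disutility: pembrolizumab trAEs (grade 1/2)",
     type: absolute, low: 0.02, high: 0.14, distribution: uniform}
  - {id: du34_pem, label: "Disutility: pembrolizumab trAEs (grade 3/4)",
     type: absolute, low: 0.08, high: 0.22, distribution: uniform}
  - {id: du12_pac, label: "Disutility: paclitaxel trAEs (grade 1/2)",
     type: absolute, low: 0.05, high: 0.13, distribution: uniform}
  - {id: du34_pac, label: "Disutility: paclitaxel trAEs (grade 3/4)",
     type: absolute, low: 0.06, high: 0.37, distribution: uniform}
  - {id: du12_ram_pac, label: "Disutility: ramucirumab + paclitaxel trAEs (grade 1/2)",
     type: absolute, low: 0.00, high: 0.24, distribution: uniform}
  - {id: du34_ram_pac, label: "Disutility: ramucirumab + paclitaxel trAEs (grade 3/4)",
     type: absolute, low: 0.16, high: 0.35, distribution: uniform}
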