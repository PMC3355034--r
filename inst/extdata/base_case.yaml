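# Base-case model configuration: posaconazole versus standard azole therapy
# (SAT; fluconazole 81% / itraconazole 19%) for prophylaxis of invasive
# fungal infection in high-risk neutropenic patients (AML/MDS).
# All monetary values are EUR at the November-2009 price level.
#
# Clinical probabilities below are the published (rounded) base-case values;
# effective_base_case() substitutes the values implied by the 75%/125%
# one-way ranges (e.g. posaconazole p_ifi 0.05 -> 0.0458).

strategies:
  posaconazole:
    clinical:
      p_ifi: 0.05              # proven/probable IFI within 100 days
      p_death_ifi: 0.36        # death given IFI, within 100 days
      p_death_other: 0.16      # non-IFI death within 100 days
      mean_days_to_ifi: 41     # mean time to IFI onset (days)
    components:
      - name: posaconazole
        drug_cost_per_day: 90.00
        prep_admin_monitor_cost_per_day: 13.69
        duration_days: 29
        weight: 1.0
  sat:
    clinical:
      p_ifi: 0.11
      p_death_ifi: 0.48
      p_death_other: 0.16
      mean_days_to_ifi: 25
    components:
      - name: fluconazole
        drug_cost_per_day: 8.00
        prep_admin_monitor_cost_per_day: 8.93
        duration_days: 24
        weight: 0.81
      - name: itraconazole
        drug_cost_per_day: 8.95
        prep_admin_monitor_cost_per_day: 12.90
        duration_days: 29
        weight: 0.19

shared:
  c_ifi: 67984                 # cost of managing one IFI episode (EUR)
  rs_aml: 0.21                 # relative survival, AML
  rs_mds: 0.08                 # relative survival, MDS
  rs_basis_years: 5            # horizon over which rs is interpreted
  aml_fraction: 0.85           # cohort AML:MDS mix -- calibration assumption,
                               # not a published value
  discount_rate: 0.03          # annual, applied after the first year
  wtp_threshold: 30000         # EUR per life-year saved
  horizon_years: 50
  acute_days: 100

# Published one-way (75%/125%) sensitivity ranges; also the source for the
# effective base-case back-calculation.
ranges:
  posaconazole.p_ifi: [0.0344, 0.0573]
  sat.p_ifi: [0.0825, 0.1375]
  posaconazole.p_death_ifi: [0.2678, 0.4464]
  sat.p_death_ifi: [0.3636, 0.6060]
  p_death_other: [0.1185, 0.1975]
  cost_per_day.posaconazole: [77.77, 129.61]
  cost_per_day.fluconazole: [12.70, 21.16]
  cost_per_day.itraconazole: [16.39, 27.31]
  c_ifi: [50988, 84980]

# One-way deterministic sensitivity grid (the IFI probabilities use the
# published wider bands; discount rate is varied 0%/5%).
dsa_scenarios:
  posaconazole.p_ifi: [0.025, 0.075]
  sat.p_ifi: [0.075, 0.15]
  posaconazole.p_death_ifi: [0.2678, 0.4464]
  sat.p_death_ifi: [0.3636, 0.6060]
  p_death_other: [0.1185, 0.1975]
  rs_aml: [0.16, 0.26]
  rs_mds: [0.06, 0.10]
  cost_per_day.posaconazole: [77.77, 129.61]
  cost_per_day.fluconazole: [12.70, 21.16]
  cost_per_day.itraconazole: [16.39, 27.31]
  c_ifi: [50988, 84980]
  discount_rate: [0.00, 0.05]

# PSA sampling distributions (family + SD as published; sd 0 => fixed).
# The IFI episode cost row names a Gamma but prints no SD; a 25% CV is used,
# consistent with the +/-25% convention of every deterministic range.
psa:
  posaconazole.p_ifi: {family: beta, sd: 0.0120}
  sat.p_ifi: {family: beta, sd: 0.0181}
  posaconazole.p_death_ifi: {family: beta, sd: 0.1247}
  sat.p_death_ifi: {family: beta, sd: 0.0857}
  p_death_other: {family: beta, sd: 0.0148}
  c_ifi: {family: gamma, cv: 0.25}
  rs_aml: {family: gamma, sd: 0.0}
  rs_mds: {family: gamma, sd: 0.0}
  cost_per_day.posaconazole: {family: gamma, sd: 0.0}
  cost_per_day.fluconazole: {family: gamma, sd: 0.0}
  cost_per_day.itraconazole: {family: gamma, sd: 0.0}
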