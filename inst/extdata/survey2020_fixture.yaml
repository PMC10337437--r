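# Aggregate counts transcribed from a 2020 population-based T2D survey of
# adults aged >=40 in five Cambodian operational districts. Individual-level
# records reconstructed from these counts are synthetic representatives.
total_n: 5072
raised_fbg: 614
cascade:
  prevalence: 560
  tested: 353
  diagnosed: 309
  in_care: 279
  in_treatment: 273
  under_control: 60
advice_bundle: 130
provider:
  public: 121
  private: 177
  other: 11
covariates:
  age_group:
    levels: ["40-49", "50-59", "60+"]
    diagnosed: [29, 125, 155]
    undiagnosed: [55, 94, 102]
  sex:
    levels: [male, female]
    diagnosed: [67, 242]
    undiagnosed: [75, 176]
  marital:
    levels: [married_or_with_spouse, widowed_or_not_with_spouse, never]
    diagnosed: [204, 102, 3]
    undiagnosed: [169, 77, 5]
  education:
    levels: [none_or_less_than_primary, primary, secondary_or_higher]
    diagnosed: [95, 179, 35]
    undiagnosed: [69, 147, 35]
  wealth_quintile:
    levels: ["1", "2", "3", "4", "5"]
    diagnosed: [48, 54, 67, 67, 73]
    undiagnosed: [52, 48, 47, 46, 58]
  setting:
    levels: [coexistence, community_based, health_center_based,
             health_center_with_context, hospital_based]
    diagnosed: [51, 58, 60, 62, 78]
    undiagnosed: [51, 54, 57, 41, 48]
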