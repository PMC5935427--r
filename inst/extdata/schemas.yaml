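# Machine-readable schemas for the three delimited/structured input families.
# All files are UTF-8; CSVs carry a header row; money is CNY at full
# precision; counts are non-negative integers.
encounters:
  format: csv
  columns:
    institution_id: {type: string, required: true}
    age_years: {type: integer, min: 0, max: 120, required: true}
    sex: {type: string, required: false}
    icd10_code:
      type: string
      pattern: "^[A-Za-z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$"
      required: false
      note: empty codes are kept and classified as unclassified
    service_type:
      type: enum
      values: [outpatient_curative, outpatient_preventive, inpatient, public_health]
    bed_days: {type: integer, min: 0, note: positive only for inpatient}
    total_cost: {type: money, min: 0}
    pay_social_insurance: {type: money, min: 0}
    pay_commercial_insurance: {type: money, min: 0}
    pay_donation: {type: money, min: 0}
    pay_government_program: {type: money, min: 0}
    pay_out_of_pocket: {type: money, min: 0}
  row_invariants:
    - payer components sum to total_cost within 1e-6 relative tolerance
    - bed_days > 0 implies service_type == inpatient
institution_finance:
  format: csv
  columns:
    institution_id: {type: string, unique: true}
    provider_type:
      type: enum
      values: [provincial_hospital, general_hospital, specialized_hospital,
               tcm_hospital, maternal_child_center,
               outpatient_service_institution, township_hospital,
               community_health_center, village_or_individual_clinic,
               public_health_institution]
    city: {type: string}
    outpatient_income: {type: money, min: 0}
    preventive_outpatient_income: {type: money, min: 0, note: "<= outpatient_income"}
    inpatient_income: {type: money, min: 0}
    basic_subsidy: {type: money, min: 0}
    outpatient_project_subsidy: {type: money, min: 0}
    inpatient_project_subsidy: {type: money, min: 0}
    superior_institution_subsidy: {type: money, min: 0}
    science_education_income: {type: money, min: 0}
    other_income: {type: money, min: 0}
    assistant_service_cost: {type: money, min: 0}
    medicine_cost: {type: money, min: 0}
    management_cost: {type: money, min: 0}
    capital_expenditure: {type: money, min: 0, note: excluded from CHE}
prevention_projects:
  format: csv
  columns:
    institution_id: {type: string}
    project_id: {type: string}
    income: {type: money, min: 0}
    expense: {type: money, min: 0}
provincial_aggregates:
  format: yaml
  keys:
    year: {type: integer, required: false}
    exchange_rate_cny_per_usd:
      type: number
      min_exclusive: 0
      default: 6.20
    strata:
      type: list
      item_keys: [provider_type, outpatient_income, inpatient_income,
                  outpatient_visits, inpatient_bed_days, basic_subsidy,
                  outpatient_project_subsidy, inpatient_project_subsidy]
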