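# Model A family: 2-compartment parent + 1-compartment metabolite, lagged
# first-order absorption, allometric body-weight scaling, no mixture.
# All numeric values are REPRESENTATIVE fixture values chosen to give
# realistic pediatric concentration ranges; they are not published estimates.
label: A
analytes:
  - {name: risperidone, molecular_weight: 410.485, role: parent}
  - {name: 9-OH-risperidone, molecular_weight: 425.91, role: metabolite}
structure: {parent_compartments: 2, has_metabolite: true, lag: true}
theta:
  CL: 25.0     # L/h per 70 kg
  V: 150.0     # L per 70 kg
  ka: 1.0      # 1/h
  ALAG: 0.35   # h
  Q: 10.0      # L/h per 70 kg
  Vp: 120.0    # L per 70 kg
  fm: 0.45
  CLm: 8.0     # L/h per 70 kg
  Vm: 180.0    # L per 70 kg
  F: 1.0
omega:         # lower triangle, variances of log-normal random effects
  CL: [0.35]
  V: [0.0, 0.20]
  CLm: [0.0, 0.0, 0.20]
covariates:
  - {parameter: CL, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: Q, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: CLm, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: V, covariate: wt, form: power, reference: 70, exponent: 1}
  - {parameter: Vp, covariate: wt, form: power, reference: 70, exponent: 1}
  - {parameter: Vm, covariate: wt, form: power, reference: 70, exponent: 1}
error:
  risperidone: {additive: 0.00024, proportional: 0.25}       # nmol/mL, fraction
  9-OH-risperidone: {additive: 0.00024, proportional: 0.22}
scale: natural
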