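# Model D family: Model C plus allometric body-weight scaling (fixed
# exponents 0.75 on clearances, 1 on volumes, 70 kg reference).
# All numeric values are REPRESENTATIVE fixture values, not published
# estimates.
label: D
analytes:
  - {name: risperidone, molecular_weight: 410.485, role: parent}
  - {name: 9-OH-risperidone, molecular_weight: 425.91, role: metabolite}
structure: {parent_compartments: 1, has_metabolite: true, lag: false}
theta:
  CL: 20.0
  V: 100.0
  ka: 1.0
  fm: 0.13
  CLm: 5.0
  Vm: 140.0
  F: 1.0
omega:
  CL: [0.25]
  V: [0.0, 0.15]
  CLm: [0.0, 0.0, 0.20]
mixture:
  proportions: {poor: 0.08, intermediate: 0.32, normal: 0.60}
  overrides:
    poor: {CL: 4.0, fm: 0.16}
    intermediate: {CL: 11.0, fm: 1.0}
    normal: {CL: 20.0, fm: 0.13}
covariates:
  - {parameter: CL, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: CLm, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: V, covariate: wt, form: power, reference: 70, exponent: 1}
  - {parameter: Vm, covariate: wt, form: power, reference: 70, exponent: 1}
error:
  risperidone: {additive: 0.00024, proportional: 0.28}
  9-OH-risperidone: {additive: 0.00024, proportional: 0.24}
scale: natural
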