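# Model B family: pediatric 1-compartment parent + 1-compartment metabolite,
# first-order absorption, three-subpopulation mixture on clearance and
# fraction metabolized (poor / intermediate / normal metabolizers),
# allometric body-weight scaling.
# All numeric values are REPRESENTATIVE fixture values, not published
# estimates.
label: B
analytes:
  - {name: risperidone, molecular_weight: 410.485, role: parent}
  - {name: 9-OH-risperidone, molecular_weight: 425.91, role: metabolite}
structure: {parent_compartments: 1, has_metabolite: true, lag: false}
theta:
  CL: 18.0
  V: 120.0
  ka: 1.2
  fm: 0.13
  CLm: 6.0
  Vm: 160.0
  F: 1.0
omega:
  CL: [0.30]
  V: [0.0, 0.20]
  CLm: [0.0, 0.0, 0.25]
mixture:
  proportions: {poor: 0.10, intermediate: 0.35, normal: 0.55}
  overrides:
    poor: {CL: 3.0, fm: 0.16}
    intermediate: {CL: 9.0, fm: 1.0}
    normal: {CL: 18.0, fm: 0.13}
covariates:
  - {parameter: CL, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: CLm, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: V, covariate: wt, form: power, reference: 70, exponent: 1}
  - {parameter: Vm, covariate: wt, form: power, reference: 70, exponent: 1}
error:
  risperidone: {additive: 0.00024, proportional: 0.30}
  9-OH-risperidone: {additive: 0.00024, proportional: 0.25}
scale: natural
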