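# Model E family: 2-compartment parent only (no metabolite), lagged
# first-order absorption, two-subpopulation mixture on clearance,
# allometric scaling, residual error on the log scale.
# All numeric values are REPRESENTATIVE fixture values, not published
# estimates.
label: E
analytes:
  - {name: risperidone, molecular_weight: 410.485, role: parent}
structure: {parent_compartments: 2, has_metabolite: false, lag: true}
theta:
  CL: 22.0
  V: 140.0
  ka: 0.9
  ALAG: 0.25
  Q: 12.0
  Vp: 150.0
  F: 1.0
omega:
  CL: [0.30]
  V: [0.0, 0.20]
mixture:
  proportions: {poor: 0.12, normal: 0.88}
  overrides:
    poor: {CL: 4.0}
    normal: {CL: 22.0}
covariates:
  - {parameter: CL, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: Q, covariate: wt, form: power, reference: 70, exponent: 0.75}
  - {parameter: V, covariate: wt, form: power, reference: 70, exponent: 1}
  - {parameter: Vp, covariate: wt, form: power, reference: 70, exponent: 1}
error:
  risperidone: {additive: 0.30}   # sd of log concentration
scale: log
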