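# Example variable-dichotomization config.
# Each entry maps a raw cohort column to one reported binary variable.
variables:
  - name: age_lt30
    variable: age
    block: personal
    success: {op: lt, value: 30}
  - name: icu_admission
    variable: icu
    block: process
    success: {op: equals, value: "1"}
  - name: dc_procedure            # denominator restricted to abortion cases
    variable: procedure
    block: process
    success: {op: equals, value: "D&C"}
    subpopulation: {variable: abortion_case, op: equals, value: "1"}
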