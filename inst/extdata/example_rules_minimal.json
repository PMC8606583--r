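{
  "tool": "oddsrules",
  "format": "rule-model/1",
  "model_class": "minimal",
  "p_max": 0,
  "bonferroni": false,
  "n_tests": 13,
  "decision_boundary": 1.015,
  "transcribed": true,
  "rules": [
    {
      "variable_type": "ethnicity",
      "code": "Black/African American",
      "or": 0.58,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "ethnicity",
      "code": "Hispanic/Latino",
      "or": 0.47,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "ethnicity",
      "code": "Unable to obtain",
      "or": 2.25,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "ethnicity",
      "code": "Unknown",
      "or": 4.59,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "gender",
      "code": "Female",
      "or": 0.8,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "gender",
      "code": "Male",
      "or": 1.25,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "insurance_type",
      "code": "Medicaid",
      "or": 0.57,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "insurance_type",
      "code": "Medicare",
      "or": 2.4,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "insurance_type",
      "code": "Other",
      "or": 0.5,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "language",
      "code": "English",
      "or": 0.73,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "language",
      "code": "Other",
      "or": 1.36,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "marital_status",
      "code": "Single",
      "or": 0.5,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    },
    {
      "variable_type": "marital_status",
      "code": "Widowed",
      "or": 2.05,
      "p_value": 0,
      "a": null,
      "b": null,
      "c": null,
      "d": null
    }
  ]
}
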