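# fictional emergency-department patient for the worked scoring example
# outcome is deliberately blank: the case is prediction input, not training data
case_id	variable_type	code	outcome
patient_1	ethnicity	Black/African American	
patient_1	gender	Female	
patient_1	insurance_type	Medicaid	
patient_1	language	English	
patient_1	marital_status	Single	
patient_1	diagnosis	Acidosis	
patient_1	diagnosis	Anuria and oliguria	
patient_1	prescription	Sodium Bicarbonate	
patient_1	prescription	Furosemide	
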