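problem	observations	outcome_events	outcome_pct
mortality	3836184	36952	1
readmission	206995	20202	9.8
dementia	287208	4674	1.6
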