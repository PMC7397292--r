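outcome	or	estimate	se	pvalue_display	or_decimals	ci_low	ci_high
Alzheimers Disorder	0.875	-0.133	0.145	0.359	3	NA	NA
Bipolar Disorder	1.402	0.338	0.234	0.149	3	NA	NA
Schizophrenia	1.132	0.124	0.182	0.496	3	NA	NA
Depression	0.984	-0.016	0.02	0.437	3	NA	NA
Rheumatoid Arthritis	1.69	0.525	0.226	0.020	3	0.083	0.967
Gout	0.469	-0.757	0.221	0.001	3	-1.189	-0.324
Type 2 Diabetes	0.769	-0.262	0.133	0.048	3	-0.522	-0.002
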