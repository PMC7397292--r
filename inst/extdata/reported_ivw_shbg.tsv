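outcome	or	estimate	se	pvalue_display	or_decimals	ci_low	ci_high	egger_intercept	egger_intercept_pvalue
Alzheimers Disorder	0.998	-0.002	0.029	0.935	3	NA	NA	0.013	0.015
Bipolar Disorder	0.991	-0.009	0.085	0.920	3	NA	NA	0.007	0.664
Schizophrenia	1.038	0.038	0.053	0.176	3	NA	NA	-0.004	0.672
Depression	1.02	0.02	0.006	0.001	2	0.008	0.031	0.002	0.092
Rheumatoid Arthritis	1.329	0.285	0.06	<0.001	3	0.141	0.429	0.022	0.12
Gout	0.971	-0.029	0.064	0.649	3	NA	NA	0.005	0.683
Type 2 Diabetes	0.887	-0.119	0.03	0.003	3	-0.203	-0.035	-0.027	0.607
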