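variable	type	group	n	mean	sd	events
Age	continuous	HC	30	62.8	9.4	NA
Age	continuous	CCQS	44	67.2	7.7	NA
Age	continuous	QSBS	37	67.5	7.8	NA
BMI	continuous	HC	30	24.7	2.9	NA
BMI	continuous	CCQS	44	24.1	3.9	NA
BMI	continuous	QSBS	37	25.2	3.3	NA
TC	continuous	HC	30	5.2	1.0	NA
TC	continuous	CCQS	44	4.4	1.0	NA
TC	continuous	QSBS	37	4.3	0.9	NA
TG	continuous	HC	30	1.4	0.9	NA
TG	continuous	CCQS	44	1.5	0.8	NA
TG	continuous	QSBS	37	1.6	0.7	NA
HDL	continuous	HC	30	1.5	0.3	NA
HDL	continuous	CCQS	44	1.2	0.2	NA
HDL	continuous	QSBS	37	1.3	0.3	NA
LDL	continuous	HC	30	3.1	0.8	NA
LDL	continuous	CCQS	44	2.6	0.8	NA
LDL	continuous	QSBS	37	2.5	0.7	NA
Albumin	continuous	HC	30	44.0	2.1	NA
Albumin	continuous	CCQS	44	44.1	2.7	NA
Albumin	continuous	QSBS	37	45.0	5.9	NA
Glucose	continuous	HC	30	5.8	1.2	NA
Glucose	continuous	CCQS	44	6.8	1.9	NA
Glucose	continuous	QSBS	37	6.6	1.7	NA
UricAcid	continuous	HC	30	305.0	80.2	NA
UricAcid	continuous	CCQS	44	318.4	79.9	NA
UricAcid	continuous	QSBS	37	344.3	81.0	NA
Female	categorical	HC	30	NA	NA	17
Female	categorical	CCQS	44	NA	NA	25
Female	categorical	QSBS	37	NA	NA	21
Arrhythmia	categorical	HC	30	NA	NA	6
Arrhythmia	categorical	CCQS	44	NA	NA	6
Arrhythmia	categorical	QSBS	37	NA	NA	6
DiabetesMellitus	categorical	HC	30	NA	NA	1
DiabetesMellitus	categorical	CCQS	44	NA	NA	20
DiabetesMellitus	categorical	QSBS	37	NA	NA	15
Hypertension	categorical	HC	30	NA	NA	5
Hypertension	categorical	CCQS	44	NA	NA	28
Hypertension	categorical	QSBS	37	NA	NA	28
Hyperlipidemia	categorical	HC	30	NA	NA	4
Hyperlipidemia	categorical	CCQS	44	NA	NA	26
Hyperlipidemia	categorical	QSBS	37	NA	NA	24
CerebrovascularDisease	categorical	HC	30	NA	NA	2
CerebrovascularDisease	categorical	CCQS	44	NA	NA	4
CerebrovascularDisease	categorical	QSBS	37	NA	NA	15
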