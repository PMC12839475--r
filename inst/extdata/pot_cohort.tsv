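patient	age_years	sex	weight_kg	duration_years	tremor_frequency_hz	medication
1	79	M	77	7	14.31	None
2	82	M	98	11	14.89	Gabapentin 1200 mg 3 times a day
3	72	F	55	4	15.31	Gabapentin 200 mg 2 times a day
4	51	F	66	2	16.00	None
5	74	M	78	7	15.41	Clonazepam 0.5 mg 2 times a day
6	66	F	72	11	14.40	Gabapentin 200 mg once a day
7	68	M	80	16	14.24	Propranolol 10 mg 3 times a day
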