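variable	n1	mean1	sd1	n2	mean2	sd2	t_printed
age	20	13.25	2.87	17	13.42	3.21	-0.17
iq	20	98.50	14.33	17	103.35	10.15	-1.17
fmri_fd	20	0.106	0.035	17	0.096	0.042	0.76
censored_timepoints	20	3.85	1.69	17	3.35	1.84	0.86
dwi_fd	20	0.609	0.155	17	0.546	0.160	1.21
srs_total	20	104.25	24.92	17	18.41	11.57	13.04
srs_awareness	20	13.10	4.39	17	3.82	2.83	7.48
srs_cognition	20	17.85	6.02	17	2.94	2.77	9.39
srs_communication	20	34.95	10.36	17	5.88	4.48	10.72
srs_motivation	20	17.80	4.12	17	3.94	2.44	12.15
srs_mannerisms	20	22.05	7.86	17	1.82	2.77	10.08
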