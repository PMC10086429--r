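exposure	mediator	outcome	beta_c	c_low	c_high	beta_a	a_low	a_high	beta_b	b_low	b_high	med_effect	med_low	med_high	med_p	prop_pct	prop_low	prop_high
EduYears	BMI	EC	-0.444	-0.822	-0.067	-0.171	-0.217	-0.126	0.408	0.102	0.715	-0.070	-0.126	-0.014	1.39e-02	15.75	3.20	28.29
EduYears	Smoking	EC	-0.444	-0.822	-0.067	-0.281	-0.342	-0.220	0.224	0.022	0.426	-0.063	-0.121	-0.004	3.49e-02	14.15	1.01	27.29
EduYears	BMI	BE	-0.145	-0.282	-0.008	-0.171	-0.217	-0.126	0.131	0.019	0.243	-0.022	-0.042	-0.002	2.87e-02	15.46	1.61	29.30
EduYears	Smoking	BE	-0.145	-0.282	-0.008	-0.281	-0.342	-0.220	0.087	0.016	0.158	-0.024	-0.045	-0.004	2.02e-02	16.85	2.63	31.08
EduYears	BMI	GERD	-0.473	-0.546	-0.400	-0.171	-0.217	-0.126	0.144	0.028	0.165	-0.025	-0.041	-0.009	2.79e-03	5.23	1.80	8.66
EduYears	Smoking	GERD	-0.473	-0.546	-0.400	-0.281	-0.342	-0.220	0.076	0.033	0.118	-0.021	-0.034	-0.008	1.11e-03	4.49	1.79	7.19
EduYears	MDD	GERD	-0.473	-0.546	-0.400	-0.232	-0.321	-0.143	0.102	0.069	0.134	-0.024	-0.035	-0.012	9.17e-05	4.98	2.48	7.48
College	BMI	GERD	-0.075	-0.119	-0.030	-0.051	-0.070	-0.031	0.173	0.062	0.206	-0.009	-0.015	-0.003	3.22e-03	11.72	3.92	19.51
College	Smoking	GERD	-0.075	-0.119	-0.030	-0.069	-0.097	-0.040	0.067	0.025	0.110	-0.005	-0.008	-0.001	9.43e-03	6.17	1.51	10.82
College	MDD	GERD	-0.075	-0.119	-0.030	-0.059	-0.100	-0.018	0.111	0.077	0.144	-0.007	-0.012	-0.002	9.40e-03	8.77	2.15	15.39
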