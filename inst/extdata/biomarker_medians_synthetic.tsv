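biomarker	unit	Normal	PV	PMF
IL-1b	pg/ml	3.3175539217873	3.37849557279396	3.72477355539371
IL-1RA	pg/ml	177.327812292069	194.64105923882	189.98338489866
IL-2R	pg/ml	384.250059774041	392.978812942007	412.665857779396
IL-6	pg/ml	5.29916486360553	7.56762071201329	6.15156845800496
IL-8	pg/ml	4.32129818321288	5.14525663114866	5.65776924597488
IL-10	pg/ml	4.95250974962399	5.32463862313858	5.5634396414276
IL-12	pg/ml	6.3993964472594	7.19450949550702	7.5744244234064
CRP	mg/l	2.94678570235254	4.58520021829057	5.99989570115399
LDH	U/l	197.274575290783	195.823210403447	199.303890760009
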