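phenotype	count	description
HCM	708	hypertrophic cardiomyopathy
DCM	479	dilated cardiomyopathy
ARVC	90	arrhythmogenic right ventricular cardiomyopathy
LVNC	54	left ventricular noncompaction
RCM	25	restrictive cardiomyopathy
NOS	61	cardiomyopathy NOS or combined features
other	8	cardiomyopathy with skeletal myopathy features
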