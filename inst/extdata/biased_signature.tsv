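gene_symbol	direction	unique_met
PLAT	up	TRUE
PLAU	up	TRUE
IL8	up	TRUE
CCL2	up	FALSE
ITGB1	up	FALSE
ACTB	up	FALSE
VCL	up	FALSE
DBN1	up	TRUE
MSN	up	TRUE
TFPI2	up	TRUE
CAV1	up	FALSE
CAV2	up	TRUE
TNC	up	TRUE
TGFBI	down	FALSE
SERPINE2	down	FALSE
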