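gene_id	group	direction	paralog_family	weight
lamp2a_c31	effector	+1	lamp2a	
lamp2a_c14	effector	+1	lamp2a	
hspa8a	effector	+1	hspa8	
hspa8b	effector	+1	hspa8	
hsp90aa1.1	effector	+1	hsp90aa1	
hsp90aa1.2	effector	+1	hsp90aa1	
phlpp1	positive_modulator	+1	phlpp1	
nfe2l2	positive_modulator	+1	nfe2l2	
akt1a	negative_modulator	-1	akt1	
akt1b	negative_modulator	-1	akt1	
rictor	negative_modulator	-1	rictor	
ctsa	negative_modulator	-1	ctsa	
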