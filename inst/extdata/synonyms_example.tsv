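term	canonical	vocabulary_id
antibiotic	antimicrobial	D000900
antibacterial	antimicrobial	D000900
anti-infective	antimicrobial	D000890
crp	c_reactive_protein	D002097
c-reactive_protein	c_reactive_protein	D002097
scr	creatinine	D003404
egfr	glomerular_filtration_rate	D005919
wbc	leukocyte_count	D007958
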