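chrom	start	end	name	role
chr15	51630100	51630400	PII	PII
chr15	51578600	51579320	PI.f_7	PIf_7
chr15	51578120	51579800	PI.f_15	PIf_15
chr15	51500600	51506000	control	control
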