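genotype,n_env_low,n_env_high
CC,279,266
CT,373,314
TT,128,117
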