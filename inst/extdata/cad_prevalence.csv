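label,k,m
nonanginal chest pain,146,913
atypical angina,963,1931
typical angina,1874,2108
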