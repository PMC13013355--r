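category,tp,fn,fp
T,411,14,22
N,828,25,37
M,548,30,196
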