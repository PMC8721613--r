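RPS4Y1	chrY
DDX3Y	chrY
PRKY	chrY
USP9Y	chrY
KDM5D	chrY
ZFY	chrY
EIF1AY	chrY
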