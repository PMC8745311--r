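test,DR,NODR,UNG
DR,455,379,33
NODR,80,1582,64
UNG,118,499,310
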