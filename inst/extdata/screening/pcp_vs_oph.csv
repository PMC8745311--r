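test,DR,NODR,UNG
DR,373,233,25
NODR,214,2005,209
UNG,66,222,173
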