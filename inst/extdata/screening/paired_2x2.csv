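rater,tp,fp,fn,tn
ALG,418,351,75,1491
PCP,300,200,193,1642
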