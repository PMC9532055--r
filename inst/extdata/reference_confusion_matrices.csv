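evaluation,TN,FP,FN,TP
cv,1282,239,318,1154
test,139,11,19,107
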