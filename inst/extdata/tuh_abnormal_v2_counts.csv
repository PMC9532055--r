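subset,class,files,patients
training,normal,1371,1237
training,pathological,1346,893
testing,normal,150,148
testing,pathological,126,105
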