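label,atpase_rate,reca_uM
TGG,10.0,1
TTG,17.5,1
TTT,25.0,1
TCA,21.0,1
CCA,30.0,1
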