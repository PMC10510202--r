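label,n,mean,sd
transdiagnostic,195,85.26,15.54
MNI152,1,78.16,0
Ernie,1,81.46,0
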