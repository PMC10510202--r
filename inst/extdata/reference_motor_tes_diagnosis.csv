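label,n,mean,sd
healthy,31,0.343,0.059
alcohol_use,87,0.341,0.064
tobacco_use,31,0.376,0.098
anxiety,25,0.35,0.082
depression,21,0.327,0.08
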