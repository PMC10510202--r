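label,n,mean,sd
healthy,31,79.23,13.11
alcohol_use,87,76.35,12.43
tobacco_use,31,87.3,17.74
anxiety,25,88.75,13.44
depression,21,78.3,17.25
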