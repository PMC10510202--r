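label,n,mean,sd
healthy,31,0.31,0.052
alcohol_use,87,0.291,0.057
tobacco_use,31,0.318,0.087
anxiety,25,0.289,0.062
depression,21,0.299,0.07
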