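label,n,mean,sd
healthy,31,84.2,14.48
alcohol_use,87,81.6,13.66
tobacco_use,31,90.96,15.52
anxiety,25,95.76,15.9
depression,21,81.11,17.17
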