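system,n_states,n_replicas,length_us
PTP1B,4,8,1.5
SHP-1,4,8,1.5
SHP-2,4,8,1.5
YopH,4,8,1.5
SHP-1-A323T,4,8,1.5
SHP-1-T501M,4,8,1.5
SHP-2-N308D,4,8,1.5
SHP-2-Q506P,4,8,1.5
SHP-1-FL-autoinhibited,1,5,1.0
SHP-1-FL-open,1,5,1.0
SHP-2-FL-autoinhibited,1,5,1.0
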