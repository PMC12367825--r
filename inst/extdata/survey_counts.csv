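device,lt5_pct,b5_10_pct,b11_20_pct,gt20_pct
AV,11,29,30,30
AV2,51,35,14,0
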