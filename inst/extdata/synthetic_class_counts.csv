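label,count
siteA,1500
siteB,600
siteC,50
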