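response,AP,NTproBNP,proteinuria,CRP
AP,0.46,0.00,0.00,1.40
NTproBNP,6.48,0.06,0.01,-8.55
proteinuria,31.76,0.07,0.11,-9.42
CRP,-0.02,-0.00,0.00,0.70
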