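[{"term_names":["psc","!snp001_R"],"beta":1.09861228866811,"term":[-1,9],"key":"-1 9"}]
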