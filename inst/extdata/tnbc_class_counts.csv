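fluid,pathogenic,likely_pathogenic,VUS,likely_benign,benign
plasma,77,98,1022,20,5
urine,71,204,1819,17,6
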