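"target","ct","amount","replicate","role"
"transgene",23.55,6.25,"d","dilution"
"transgene",22.5,12.5,"d","dilution"
"transgene",21.594,25,"d","dilution"
"transgene",20.655,50,"d","dilution"
"reference",24.337,6.25,"d","dilution"
"reference",23.297,12.5,"d","dilution"
"reference",22.363,25,"d","dilution"
"reference",21.268,50,"d","dilution"
"transgene",24.101,NA,"r1","calibrator"
"transgene",23.997,NA,"r2","calibrator"
"transgene",24.065,NA,"r3","calibrator"
"reference",25.114,NA,"r1","calibrator"
"reference",24.931,NA,"r2","calibrator"
"reference",24.986,NA,"r3","calibrator"
"transgene",23.041,NA,"r1","sample"
"transgene",23.079,NA,"r2","sample"
"transgene",23.033,NA,"r3","sample"
"reference",24.867,NA,"r1","sample"
"reference",24.878,NA,"r2","sample"
"reference",25.066,NA,"r3","sample"
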