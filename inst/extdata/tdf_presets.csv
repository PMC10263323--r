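name,mean_dC,sd_dC,mean_dN,sd_dN,provenance
TDF1,0.49,4.7,4.43,1.32,calculated
TDF2,0.8,1.1,3,2.6,published
TDF3,0.91,1.04,3.41,0.2,published
TDF4,1.85,0,2.54,0,published
TDF5,2.8,1.5,5.14,1.35,published
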