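source_name,biomass_mgC_m2
Lumbriculus variegatus,520
Tubifex tubifex,45
Limnodrilus hoffmeisteri,610
Daphnia ambigua,85
Leptodiaptomus cuauhtemoci,38
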