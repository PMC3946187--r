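name	forward	reverse	marker
LCO1490xHCO2198	GGTCAACAAATCATAAAGATATTGG	TAAACTTCAGGGTGACCAAAAAATCA	CO1
dgLCO1490xdgHCO2198	GGTCAACAAATCATAAAGAYATYGG	TAAACTTCAGGGTGACCAAARAAYCA	CO1
mlCOIintFxHCO2198	GGWACWGGWTGAACWGTWTAYCCYCC	TAAACTTCAGGGTGACCAAAAAATCA	CO1
mlCOIintFxdgHCO2198	GGWACWGGWTGAACWGTWTAYCCYCC	TAAACTTCAGGGTGACCAAARAAYCA	CO1
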