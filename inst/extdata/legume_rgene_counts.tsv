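species	common_name	count
cicer_arietinum	chickpea	227
cajanus_cajan	pigeonpea	815
cultivated_soybean	Glycine max	744
wild_soybean	Glycine soja	952
lotus_japonicus	birds-foot trefoil	270
medicago_truncatula	barrel clover	770
phaseolus_vulgaris	common bean	439
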