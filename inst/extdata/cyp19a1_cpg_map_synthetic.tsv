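cpg_id	chrom	position
cgCTL01	chr15	51500600
cgCTL02	chr15	51501200
cgCTL03	chr15	51501800
cgCTL04	chr15	51502400
cgCTL05	chr15	51503000
cgCTL06	chr15	51503600
cgCTL07	chr15	51504200
cgCTL08	chr15	51504800
cgCTL09	chr15	51505400
cgCTL10	chr15	51506000
cgPIF01	chr15	51578120
cgPIF02	chr15	51578240
cgPIF03	chr15	51578360
cgPIF04	chr15	51578480
cgPIF05	chr15	51578600
cgPIF06	chr15	51578720
cgPIF07	chr15	51578840
cgPIF08	chr15	51578960
cgPIF09	chr15	51579080
cgPIF10	chr15	51579200
cgPIF11	chr15	51579320
cgPIF12	chr15	51579440
cgPIF13	chr15	51579560
cgPIF14	chr15	51579680
cgPIF15	chr15	51579800
cgPII01	chr15	51630200
cgPII02	chr15	51630360
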