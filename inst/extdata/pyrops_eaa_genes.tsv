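symbiont	gene	status
sulcia	ilvB	functional
sulcia	ilvC	functional
sulcia	ilvD	functional
sulcia	ilvE	functional
sulcia	leuA	functional
sulcia	leuB	functional
sulcia	leuC	functional
sulcia	leuD	functional
vidania	aroG	functional
vidania	aroB	functional
vidania	aroD	functional
vidania	aroE	functional
vidania	aroK	functional
vidania	aroA	functional
vidania	aroC	functional
vidania	trpE	functional
vidania	trpD	functional
vidania	trpC	functional
vidania	trpA	functional
vidania	trpB	functional
vidania	hisG	functional
vidania	hisE	functional
vidania	hisI	functional
vidania	hisA	functional
vidania	hisH	functional
vidania	hisF	functional
vidania	hisB	functional
vidania	hisC	functional
vidania	hisD	functional
vidania	thrA	functional
vidania	thrB	functional
vidania	thrC	functional
vidania	asd	functional
vidania	dapA	functional
vidania	dapB	functional
vidania	dapD	functional
vidania	dapC	functional
vidania	dapE	functional
vidania	dapF	functional
vidania	lysA	functional
vidania	metC	functional
vidania	metE	functional
vidania	argF	functional
vidania	argG	functional
vidania	argH	functional
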