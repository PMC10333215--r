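eaa	step	genes
leucine	1	ilvB,ilvI
leucine	2	ilvC
leucine	3	ilvD
leucine	4	leuA
leucine	5	leuC
leucine	6	leuD
leucine	7	leuB
valine	1	ilvB,ilvI
valine	2	ilvC
valine	3	ilvD
valine	4	ilvE
isoleucine	1	ilvA
isoleucine	2	ilvB,ilvI
isoleucine	3	ilvC
isoleucine	4	ilvD
isoleucine	5	ilvE
methionine	1	metA
methionine	2	metB
methionine	3	metC
methionine	4	metE,metH
histidine	1	hisG
histidine	2	hisE
histidine	3	hisI
histidine	4	hisA
histidine	5	hisH
histidine	6	hisF
histidine	7	hisB
histidine	8	hisC
histidine	9	hisD
tryptophan	1	aroG
tryptophan	2	aroB
tryptophan	3	aroD
tryptophan	4	aroE
tryptophan	5	aroK
tryptophan	6	aroA
tryptophan	7	aroC
tryptophan	8	trpE
tryptophan	9	trpD
tryptophan	10	trpC
tryptophan	11	trpA
tryptophan	12	trpB
threonine	1	thrA,lysC
threonine	2	asd
threonine	3	thrB
threonine	4	thrC
lysine	1	thrA,lysC
lysine	2	asd
lysine	3	dapA
lysine	4	dapB
lysine	5	dapD
lysine	6	dapC
lysine	7	dapE
lysine	8	dapF
lysine	9	lysA
arginine	1	argA
arginine	2	argB
arginine	3	argC
arginine	4	argD
arginine	5	argE
arginine	6	argF
arginine	7	argG
arginine	8	argH
phenylalanine	1	aroG
phenylalanine	2	aroB
phenylalanine	3	aroD
phenylalanine	4	aroE
phenylalanine	5	aroK
phenylalanine	6	aroA
phenylalanine	7	aroC
phenylalanine	8	pheA
phenylalanine	9	aspC,tyrB
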