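((((PYRLAN,(PYRCLA,PYRVIR)),((RANSCY,CALKRU),DICMUL)),OLIH),((((AURITIBICEN,CRYPTOTYMPANA),(MUDA,MOGANNIA)),TETUND),(PSPU,ALF)));
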