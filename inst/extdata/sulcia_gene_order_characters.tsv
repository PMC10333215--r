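taxon	character	state
PYRLAN	fulgoromorpha_arrangement	1
PYRCLA	fulgoromorpha_arrangement	1
PYRVIR	fulgoromorpha_arrangement	1
RANSCY	fulgoromorpha_arrangement	1
CALKRU	fulgoromorpha_arrangement	1
DICMUL	fulgoromorpha_arrangement	1
OLIH	fulgoromorpha_arrangement	1
AURITIBICEN	fulgoromorpha_arrangement	0
CRYPTOTYMPANA	fulgoromorpha_arrangement	0
MUDA	fulgoromorpha_arrangement	0
MOGANNIA	fulgoromorpha_arrangement	0
TETUND	fulgoromorpha_arrangement	0
PSPU	fulgoromorpha_arrangement	0
ALF	fulgoromorpha_arrangement	0
PYRLAN	pyrops_inversion	1
PYRCLA	pyrops_inversion	1
PYRVIR	pyrops_inversion	1
RANSCY	pyrops_inversion	0
CALKRU	pyrops_inversion	0
DICMUL	pyrops_inversion	0
OLIH	pyrops_inversion	0
AURITIBICEN	pyrops_inversion	0
CRYPTOTYMPANA	pyrops_inversion	0
MUDA	pyrops_inversion	0
MOGANNIA	pyrops_inversion	0
TETUND	pyrops_inversion	0
PSPU	pyrops_inversion	0
ALF	pyrops_inversion	0
PYRLAN	auritibicen_inversion	0
PYRCLA	auritibicen_inversion	0
PYRVIR	auritibicen_inversion	0
RANSCY	auritibicen_inversion	0
CALKRU	auritibicen_inversion	0
DICMUL	auritibicen_inversion	0
OLIH	auritibicen_inversion	0
AURITIBICEN	auritibicen_inversion	1
CRYPTOTYMPANA	auritibicen_inversion	0
MUDA	auritibicen_inversion	0
MOGANNIA	auritibicen_inversion	0
TETUND	auritibicen_inversion	0
PSPU	auritibicen_inversion	0
ALF	auritibicen_inversion	0
PYRLAN	cryptotympana_inversion	0
PYRCLA	cryptotympana_inversion	0
PYRVIR	cryptotympana_inversion	0
RANSCY	cryptotympana_inversion	0
CALKRU	cryptotympana_inversion	0
DICMUL	cryptotympana_inversion	0
OLIH	cryptotympana_inversion	0
AURITIBICEN	cryptotympana_inversion	0
CRYPTOTYMPANA	cryptotympana_inversion	1
MUDA	cryptotympana_inversion	0
MOGANNIA	cryptotympana_inversion	0
TETUND	cryptotympana_inversion	0
PSPU	cryptotympana_inversion	0
ALF	cryptotympana_inversion	0
PYRLAN	muda_inversion	0
PYRCLA	muda_inversion	0
PYRVIR	muda_inversion	0
RANSCY	muda_inversion	0
CALKRU	muda_inversion	0
DICMUL	muda_inversion	0
OLIH	muda_inversion	0
AURITIBICEN	muda_inversion	0
CRYPTOTYMPANA	muda_inversion	0
MUDA	muda_inversion	1
MOGANNIA	muda_inversion	0
TETUND	muda_inversion	0
PSPU	muda_inversion	0
ALF	muda_inversion	0
PYRLAN	mogannia_inversion	0
PYRCLA	mogannia_inversion	0
PYRVIR	mogannia_inversion	0
RANSCY	mogannia_inversion	0
CALKRU	mogannia_inversion	0
DICMUL	mogannia_inversion	0
OLIH	mogannia_inversion	0
AURITIBICEN	mogannia_inversion	0
CRYPTOTYMPANA	mogannia_inversion	0
MUDA	mogannia_inversion	0
MOGANNIA	mogannia_inversion	1
TETUND	mogannia_inversion	0
PSPU	mogannia_inversion	0
ALF	mogannia_inversion	0
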