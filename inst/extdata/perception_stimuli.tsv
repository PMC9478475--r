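pair_id	word_a	gloss_a	word_b	gloss_b
p01	gai1	chicken	gei1	machine
p02	gai1	chicken	gaai1	street
p03	fai1	to wave	fei1	to fly
p04	do1	many	dou1	knife
p05	go1	song	gou1	tall
p06	so1	comb	sou1	beard, moustache
p07	bo1	ball	bou1	pot
p08	mau1	to squat	maau1	cat
p09	cau1	autumn	caau1	to copy
p10	kat1	cough	kaat1	card
p11	sam1	heart	saam1	shirt
p12	sai1	west	saai1	to waste
p13	gwai1	turtle	gwaai1	well-behaved
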