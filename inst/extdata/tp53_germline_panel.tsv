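exon	id	cosmic_id	novelty	hgvs_c	hgvs_p	polyphen	sift	maf_evs	maf_1000g	maf_panel	clear	cortical	nuclear	psc	mixed
4	rs1800370		reference	c.108G>A	p.P36P	synonymous	synonymous	0.0148	0.0051	0.0178	2	1	4	0	1
4	rs1042522	COSM250061	reference	c.215C>G	p.P72R	B	D	0.2548	0.2424	0.2666	60	38	64	2	46
4	rs751978853		reference	c.354A>T	p.T118T	synonymous	synonymous			0.0022	1	0	0	0	0
5	rs375275361	COSM45823	reference	c.558T>C	p.D186D	synonymous	synonymous			0.0022	0	1	0	0	0
6	rs1800372	COSM249885	reference	c.639A>G	p.R213R	synonymous	synonymous	0.0193	0.0202	0.0333	7	0	5	0	3
8	rs770598448		reference	c.789T>C	p.N263N	synonymous	synonymous			0.0022	0	0	0	0	1
8	rs730882008	COSM44470	reference	c.845G>T	p.R282L	D	D			0.0022	0	1	0	0	0
8	rs200073907	COSM45332	reference	c.885T>C	p.P295P	synonymous	synonymous			0.0044	0	0	0	0	2
11	rs765530090		reference	c.1113C>A	p.S371S	synonymous	synonymous			0.1800	24	17	26	1	13
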