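clade1	clade2	hd1	hd2	r1	r2	sign	rel_printed	log_printed	most_polyphagous_side
Somena	Kidokuga	22	7	6	2	Pos	3.00	0.477	1
Arna+Artaxa+Toxoproctis+Euproctis	Nygmia	25	15	74	55	Pos	1.35	0.129	1
Calliteara	Griveaudyria	28	1	45	2	Pos	22.5	1.352	1
Laelia	Pantana	6	1	100	33	Pos	3.03	0.481	1
Orgyia	Olene	38	25	62	26	Pos	2.39	0.377	1
Aroa	Hemerophanes	5	1	18	6	Pos	3.00	0.477	1
Lymantria	Sarsina+Crorema	34	4	170	24	Pos	7.08	0.850	1
Leucoma	Ivela+Perina+?Leucoma	12	7	46	10	Pos	4.60	0.663	1
Locharna+Kuromondokuga	Pida	8	1	9	13	Neg	0.69	-0.160	1
Eloria	Ruanda	5	1	70	3	Pos	23.3	1.368	1
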