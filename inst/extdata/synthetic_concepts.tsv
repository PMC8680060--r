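100001	prednisona
100002	corticoides
100003	paracetamol
100004	ibuprofeno
100005	amoxicilina
100006	omeprazol
100007	metformina
100008	insulina
100009	salbutamol
100010	enalapril
100011	furosemida
100012	atorvastatina
100013	tenecteplasa
100014	fentanilo
100015	heparina sodica
100016	acido acetilsalicilico
100017	calcio ionico
100018	hemoglobina
100019	hemoglobina glicosilada
100020	creatinina
100021	bilirrubina total
100022	fosfatasa alcalina
100023	lactato deshidrogenasa
100024	proteina c reactiva
100025	antigeno prostatico especifico
100026	antigeno carcino embrionario
100027	troponina
100028	ferritina
100029	transferrina
100030	albumina
100031	colesterol total
100032	trigliceridos
100033	glucosa
100034	potasio serico
100035	sodio serico
100036	urea
100037	amilasa
100038	lipasa
100039	vitamina b doce
100040	vitamina d
100041	tirotropina
100042	tiroxina libre
100043	cortisol
100044	prolactina
100045	testosterona
100046	estradiol
100047	progesterona
100048	inmunoglobulina g
100049	inmunoglobulina e
100050	factor reumatoide
100051	interleucina seis
100052	citoqueratina siete
100053	alfa fetoproteina
100054	beta gonadotropina corionica
100055	dimero d
100056	fibrinogeno
100057	plaquetas
100058	leucocitos
100059	linfocitos
100060	neutrofilos
100061	cortisol
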