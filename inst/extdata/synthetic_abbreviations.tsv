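hb	hemoglobina
hba1c	hemoglobina glicosilada
pcr	proteina c reactiva
psa	antigeno prostatico especifico
cea	antigeno carcino embrionario
ldh	lactato deshidrogenasa
fa	fosfatasa alcalina
aas	acido acetilsalicilico
tsh	tirotropina
t4l	tiroxina libre
igg	inmunoglobulina g
ige	inmunoglobulina e
fr	factor reumatoide
il6	interleucina seis
ck 7	citoqueratina siete
afp	alfa fetoproteina
bhcg	beta gonadotropina corionica
dd	dimero d
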