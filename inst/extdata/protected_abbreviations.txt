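dr
dra
sr
sra
srta
prof
etc
vs
fig
no
art
pag
tel
av
avda
cap
dpto
ej
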