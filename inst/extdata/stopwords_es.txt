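el
la
los
las
un
una
unos
unas
de
del
a
al
y
o
u
e
en
con
por
para
sin
sobre
entre
que
se
su
sus
lo
le
les
mi
tu
es
son
fue
ser
está
están
como
más
pero
no
ni
si
ya
muy
también
hasta
desde
durante
este
esta
estos
estas
ese
esa
eso
aquel
cual
cuales
donde
cuando
quien
hay
ha
han
he
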