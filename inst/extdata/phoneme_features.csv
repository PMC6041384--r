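# Binary phonological feature table for an English-subset segment inventory
# (ARPAbet-style codes). Features: cons(onantal), son(orant), cont(inuant),
# nasal, voice, lab(ial), cor(onal), dors(al), high, low, back, round, tense.
segment,cons,son,cont,nasal,voice,lab,cor,dors,high,low,back,round,tense
p,1,0,0,0,0,1,0,0,0,0,0,0,0
b,1,0,0,0,1,1,0,0,0,0,0,0,0
t,1,0,0,0,0,0,1,0,0,0,0,0,0
d,1,0,0,0,1,0,1,0,0,0,0,0,0
k,1,0,0,0,0,0,0,1,1,0,1,0,0
g,1,0,0,0,1,0,0,1,1,0,1,0,0
f,1,0,1,0,0,1,0,0,0,0,0,0,0
v,1,0,1,0,1,1,0,0,0,0,0,0,0
th,1,0,1,0,0,0,1,0,0,0,0,0,0
dh,1,0,1,0,1,0,1,0,0,0,0,0,0
s,1,0,1,0,0,0,1,0,0,0,0,0,0
z,1,0,1,0,1,0,1,0,0,0,0,0,0
sh,1,0,1,0,0,0,1,1,1,0,0,0,0
zh,1,0,1,0,1,0,1,1,1,0,0,0,0
ch,1,0,0,0,0,0,1,1,1,0,0,0,0
jh,1,0,0,0,1,0,1,1,1,0,0,0,0
m,1,1,0,1,1,1,0,0,0,0,0,0,0
n,1,1,0,1,1,0,1,0,0,0,0,0,0
ng,1,1,0,1,1,0,0,1,1,0,1,0,0
l,1,1,1,0,1,0,1,0,0,0,0,0,0
r,1,1,1,0,1,0,1,0,0,0,0,0,0
w,0,1,1,0,1,1,0,1,1,0,1,1,0
y,0,1,1,0,1,0,0,1,1,0,0,0,0
h,0,1,1,0,0,0,0,0,0,0,0,0,0
iy,0,1,1,0,1,0,0,1,1,0,0,0,1
ih,0,1,1,0,1,0,0,1,1,0,0,0,0
ey,0,1,1,0,1,0,0,1,0,0,0,0,1
eh,0,1,1,0,1,0,0,1,0,0,0,0,0
ae,0,1,1,0,1,0,0,1,0,1,0,0,0
aa,0,1,1,0,1,0,0,1,0,1,1,0,1
ah,0,1,1,0,1,0,0,1,0,0,1,0,0
ao,0,1,1,0,1,0,0,1,0,1,1,1,1
oh,0,1,1,0,1,0,0,1,0,0,1,1,1
uh,0,1,1,0,1,0,0,1,1,0,1,1,0
uw,0,1,1,0,1,0,0,1,1,0,1,1,1
er,0,1,1,0,1,0,1,1,0,0,0,0,0
ay,0,1,1,0,1,0,0,1,0,1,0,0,1
aw,0,1,1,0,1,1,0,1,0,1,1,1,1
oy,0,1,1,0,1,0,0,1,0,0,1,1,1
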