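h2o
co2
nad
nadh
nadp
nadph
fad
fadh2
atp
adp
amp
datp
dadp
damp
gtp
gdp
gmp
utp
udp
ump
ctp
cdp
cmp
coa
pi
ppi
h
o2
nh4
h2o2
so4
cl
na1
k
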