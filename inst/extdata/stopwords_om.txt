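# Default Afaan Oromo stop-word list: common function words
# (conjunctions, adpositions, pronouns, demonstratives).
# One token per line; lines starting with '#' are ignored.
# Replace freely: pass your own list to any function taking `stopwords`.
akka
ammo
ani
ati
booda
dura
eega
fi
gara
garuu
hoo
immoo
inni
isaan
isaanii
isaa
isee
ishee
isheen
isin
itti
jedhe
kan
kana
kanaaf
keenya
keessan
koo
kun
malee
moo
naaf
natti
nuti
otoo
silaa
sun
tana
waan
wajjin
yookiin
yoo
ykn
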