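# Default filler keyword set: non-lexical vocalizations ("sounds") plus stray
# single-letter tokens (every letter except the words "a" and "i").
# One term per line; replace this file to override the defaults entirely.
um
uh
er
ah
eh
hm
hmm
mm
mhm
huh
uhm
em
b
c
d
e
f
g
h
j
k
l
m
n
o
p
q
r
s
t
u
v
w
x
y
z
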