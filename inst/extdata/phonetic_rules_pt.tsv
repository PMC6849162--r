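# fonospell Brazilian-Portuguese grapheme-to-phoneme rule table, version 1
# Applied left-to-right; at each position the first matching rule wins, so
# digraphs must precede their component letters. Contexts are single-character
# regular expressions tested against the neighbouring letter, with "_"
# standing in for a word boundary; an empty context matches anything.
# phonemes: space-separated emitted symbols; "-" emits nothing (silent).
pattern	prev	next	phonemes
ch			SH
lh			LH
nh			NH
rr			RR
ss			S
qu		[ei]	K
qu			K U
gu		[ei]	G
h			-
ç			S
c		[ei]	S
c			K
g		[ei]	J
g			G
s	[aeiou]	[aeiou]	Z
s			S
z		_	S
z			Z
x	_		SH
x	[aeiou]	[aeiou]	K S
x			SH
m		[aeiou]	M
m			N
n		[aeiou]	N
n			N
w			V
y			I
k			K
q			K
r			R
b			B
d			D
f			F
j			J
l			L
p			P
t			T
v			V
a			A
e			E
i			I
o			O
u			U
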