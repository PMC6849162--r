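drug	occurrences
fluoxetina	18624
paracetamol	8697
diazepam	8474
amitriptilina	8463
omeprazol	7825
dipirona	7320
glicose	5721
captopril	5383
insulina	5290
nimesulida	4228
clorpromazina	4226
enalapril	4144
imipramina	4135
sinvastatina	3862
carbamazepina	3853
amoxicilina	3716
ibuprofeno	3714
metformina	3467
risperidona	3464
atenolol	3224
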