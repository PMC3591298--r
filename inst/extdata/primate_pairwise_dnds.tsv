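taxon_a	taxon_b	omega
Chimpanzee	Human	0.0312
Macaque	Human	0.0635
Macaque	Chimpanzee	0.0860
Gibbon	Human	0.0532
Gibbon	Chimpanzee	0.0774
Gibbon	Macaque	0.0738
Marmoset	Human	0.1272
Marmoset	Chimpanzee	0.1480
Marmoset	Macaque	0.0647
Marmoset	Gibbon	0.1101
Gorilla	Human	0.0435
Gorilla	Chimpanzee	0.0941
Gorilla	Macaque	0.0949
Gorilla	Gibbon	0.1053
Gorilla	Marmoset	0.1666
Lemur	Human	0.0487
Lemur	Chimpanzee	0.0514
Lemur	Macaque	0.0566
Lemur	Gibbon	0.0511
Lemur	Marmoset	0.0537
Lemur	Gorilla	0.0513
Galago	Human	0.0964
Galago	Chimpanzee	0.0900
Galago	Macaque	0.0742
Galago	Gibbon	0.1138
Galago	Marmoset	0.0753
Galago	Gorilla	0.0911
Galago	Lemur	0.0905
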