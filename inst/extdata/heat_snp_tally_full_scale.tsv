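category	resistant	highly_resistant
downstream	29082	14759
exon	358	185
intronic	18846	9541
missense	10194	5046
splice_acceptor	28	16
splice_donor	38	19
start_gained	769	366
start_lost	25	11
stop_gained	225	116
stop_lost	26	14
synonymous	7827	4090
upstream	66718	35970
utr3	8820	4422
utr5	3817	1880
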