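a	GO:0001	MF	4
a	GO:0002	BP	5
x	GO:0001	MF	4
x	GO:0003	BP	3
b	GO:0004	CC	2
y	GO:0004	CC	2
c	GO:0005	MF	4
z	GO:0006	MF	4
d	GO:0007	BP	3
w	GO:0007	BP	3
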