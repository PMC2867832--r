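>tata_box_synthetic (synthetic TATA-box-like count matrix; not a database motif)
A [ 10  3 90  5 88 55 85 60 48 15 10 12 ]
C [ 40  4  2  3  2  3  3  4  6 20 35 30 ]
G [ 15  3  4  4  6  4  6  6 40 55 45 48 ]
T [ 35 90  4 88  4 38  6 30  6 10 10 10 ]
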