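MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF TATA_box synthetic consensus TATAWAWR
letter-probability matrix: alength= 4 w= 8 nsites= 100 E= 0
 0.040 0.050 0.030 0.880
 0.880 0.030 0.040 0.050
 0.050 0.040 0.030 0.880
 0.900 0.020 0.030 0.050
 0.500 0.050 0.050 0.400
 0.850 0.050 0.050 0.050
 0.450 0.050 0.100 0.400
 0.350 0.100 0.450 0.100
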