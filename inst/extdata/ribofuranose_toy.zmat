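# toy ribofuranose (synthetic Z-matrix, C5H10O5)
O
C 1 1.480000
C 2 1.480000 1 108.000000
C 3 1.480000 2 108.000000 1 0.000000
C 1 1.480000 2 108.000000 3 0.000000
O 2 1.420000 1 109.838892 3 -119.774231
H 6 0.960000 2 108.000000 1 -61.353115
H 2 1.090000 1 109.838892 3 119.774231
O 3 1.420000 2 109.838892 1 119.774231
H 9 0.960000 3 108.000000 2 61.353115
H 3 1.090000 2 109.838892 1 -119.774231
O 4 1.420000 3 109.838892 2 -119.774231
H 12 0.960000 4 108.000000 3 180.000000
H 4 1.090000 3 109.838892 2 119.774231
C 5 1.520000 1 109.838892 2 119.774231
H 5 1.090000 1 109.838892 2 -119.774231
O 15 1.420000 5 109.500000 1 61.353115
H 17 0.960000 15 108.000000 5 180.000000
H 15 1.090000 5 109.500000 1 -58.646885
H 15 1.090000 5 109.500000 1 -178.646885
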