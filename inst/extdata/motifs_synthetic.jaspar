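>SYN01 synthetic_planted_dr1_like
A [   1   1 297   1   1   1   1   1 297   1 ]
C [   1   1   1 297 297   1   1   1   1 297 ]
G [   1 297   1   1   1   1   1 297   1   1 ]
T [ 297   1   1   1   1 297 297   1   1   1 ]
>SYND01 synthetic_decoy_01
A [ 38  4  7 31  6  9 ]
C [  8 41  6  9 38  7 ]
G [  7  8 40  9  8 37 ]
T [  7  7  7 11  8  7 ]
>SYND02 synthetic_decoy_02
A [  5 36  8  6 33  7  9 ]
C [ 39  7  6 35  8  8  6 ]
G [  8  9 37  9  9 36  8 ]
T [  8  8  9 10 10  9 37 ]
>SYND03 synthetic_decoy_03
A [ 33  6  9  7 30  8  6 34 ]
C [  9 35  8  6  9  7 36  8 ]
G [  9  9 34  9 11 36  8  9 ]
T [  9 10  9 38 10  9 10  9 ]
>SYND04 synthetic_decoy_04
A [  6  9 35  7  8 32  9  7 ]
C [  8 34  7  9 36  8  7  9 ]
G [ 36  8  9  8  7  9 35  8 ]
T [ 10  9  9 36  9 11  9 36 ]
>SYND05 synthetic_decoy_05
A [  7 32  9  8  6 33  8 ]
C [  9  8 34  7  9  8 35 ]
G [ 33  9  8 36  9  9  8 ]
T [ 11 11  9  9 36 10  9 ]
>SYND06 synthetic_decoy_06
A [ 31  8  7  9 30  9 ]
C [  9 33  9  8  9 32 ]
G [  9  9 35  8 11  9 ]
T [ 11 10  9 35 10 10 ]
>SYND07 synthetic_decoy_07
A [  8  7 33  9  8  7 31  9 ]
C [ 34  9  8  7 35  9  8  8 ]
G [  8 35  9  9  8 34  9  9 ]
T [ 10  9 10 35  9 10 12 34 ]
>SYND08 synthetic_decoy_08
A [  9 34  7  8 32  9  8 ]
C [  7  8 36  9  9 34  9 ]
G [ 35  9  8  9  9  8 33 ]
T [  9  9  9 34 10  9 10 ]
>SYND09 synthetic_decoy_09
A [ 36  8  9  7 33  8 ]
C [  8 34  8  9  8 35 ]
G [  8  9 33  9 10  8 ]
T [  8  9 10 35  9  9 ]
>SYND10 synthetic_decoy_10
A [  7  9 31  8  7  9 33  8 ]
C [  9 33  9  8 34  8  7  9 ]
G [ 34  8  9  9  9 33  9  9 ]
T [ 10 10 11 35 10 10 11 34 ]
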