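>RUNX
A [  1  1  1  1  1  1  1  1  1 ]
C [ 97  1  1  1  1  1  1  1  1 ]
G [  1  1 97  1 97 97  1  1  1 ]
T [  1 97  1 97  1  1 97 97 97 ]
>ETS
A [ 97  1 97  1  1 97 97  1  1 ]
C [  1 97  1  1  1  1  1  1  1 ]
G [  1  1  1 97 97  1  1 97  1 ]
T [  1  1  1  1  1  1  1  1 97 ]
>GATA
A [ 97 97  1 97  1 97 97  1  1 ]
C [  1  1  1  1  1  1  1  1  1 ]
G [  1  1 97  1  1  1  1 97 97 ]
T [  1  1  1  1 97  1  1  1  1 ]
>AP1
A [ 97  1  1 97  1  1  1 97  1 ]
C [  1  1  1  1 97  1 97  1  1 ]
G [  1  1 97  1  1  1  1  1  1 ]
T [  1 97  1  1  1 97  1  1 97 ]
>TEAD
A [ 97  1 97  1  1  1  1 97  1 ]
C [  1 97  1  1  1 97 97  1 97 ]
G [  1  1  1  1  1  1  1  1  1 ]
T [  1  1  1 97 97  1  1  1  1 ]
>ETS_RUNX
A [ 97  1 97  1  1 97 97  1  1 25 25  1  1  1  1  1  1  1  1  1 ]
C [  1 97  1  1  1  1  1  1  1 25 25 97  1  1  1  1  1  1  1  1 ]
G [  1  1  1 97 97  1  1 97  1 25 25  1  1 97  1 97 97  1  1  1 ]
T [  1  1  1  1  1  1  1  1 97 25 25  1 97  1 97  1  1 97 97 97 ]
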