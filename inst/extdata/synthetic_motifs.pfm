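>GATA GATA-like_synthetic
A [  91   3  91   3  91  91   3  91 ]
C [   3   3   3   3   3   3   3   3 ]
G [   3  91   3   3   3   3  91   3 ]
T [   3   3   3  91   3   3   3   3 ]
>CEBP CEBP-like_synthetic
A [  91   3   3   3   3   3   3  91  91   3 ]
C [   3   3   3   3  91   3  91   3   3   3 ]
G [   3   3   3  91   3  91   3   3   3   3 ]
T [   3  91  91   3   3   3   3   3   3  91 ]
>EBOX EBOX-like_synthetic
A [  91  91   3  91   3   3   3   3   3   3 ]
C [   3   3  91   3   3  91   3   3   3   3 ]
G [   3   3   3   3  91   3   3  91   3   3 ]
T [   3   3   3   3   3   3  91   3  91  91 ]
>RUNX RUNX-like_synthetic
A [   3   3   3   3   3   3   3   3 ]
C [   3   3   3   3   3   3   3   3 ]
G [   3  91   3  91  91   3   3   3 ]
T [  91   3  91   3   3  91  91  91 ]
>ETS ETS-like_synthetic
A [  91   3  91   3   3  91  91   3   3   3 ]
C [   3  91   3   3   3   3   3   3   3   3 ]
G [   3   3   3  91  91   3   3  91   3  91 ]
T [   3   3   3   3   3   3   3   3  91   3 ]
>AP1 AP1-like_synthetic
A [   3   3  91   3   3   3  91   3 ]
C [   3   3   3  91   3  91   3   3 ]
G [   3  91   3   3   3   3   3   3 ]
T [  91   3   3   3  91   3   3  91 ]
>CTCF CTCF-like_synthetic
A [   3   3  91   3   3  91   3   3   3   3   3   3   3   3 ]
C [  91  91   3  91  91   3   3   3   3   3   3  91   3  91 ]
G [   3   3   3   3   3   3  91  91  91  91  91   3  91   3 ]
T [   3   3   3   3   3   3   3   3   3   3   3   3   3   3 ]
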