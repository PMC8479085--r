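>P1
DAEFRHDSGY
>P2
HDSGYEVHHQ
>P3
EVHHQKLVFF
>P4
KLVFFAEDVG
>P5
AEDVGSNKGA
>P6
SNKGAIIGLMV
>P7
IIGLMVGGVVIA
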