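>aM1 astratide, Radix Astragali marker, 3811.8 Da peak
VDCSGACSPFEVPPCGSRDCRCIPIGLVVGFCIYPTG
>bM1 astratide, Radix Astragali marker, 4724.4 Da peak
CEKPSKFFSGPCIGSSGKTQCAYLCRRGEGLQDGNCKGLKCVCAC
>hP1 hedytide, Radix Hedysarum marker, 3944.3 Da peak
QGCNGPCTPFEQPPCGIQSCRCFPEVLFFGRCSTPSG
>hP2 hedytide, Radix Hedysarum marker, 4780.1 Da peak
CEKGSEFFVGACRYSEGTQQCATLCSRGEGLQGGKCKGVRCYCSC
>aB1 achyranthes, six-cysteine hevein-like peptide
CLESGTSCIPGAPHDCCSGVCIPIVTVFYGKCY
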