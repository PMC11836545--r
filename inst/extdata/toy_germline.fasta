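>TRBV-T01|V|48
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGTGTGCCAGCAGC
>TRBV-T02|V|48
ACGTACCCCACAGAGCTCCACCGCCTGAAACTGTATGCTGGCCCCTCCTGTGCCAGCCGG
>TRBV-T03|V|48
TCCCTGCGTACGTTGGGTGCTAGATGATAGCGGATGATTCGAGACGGATGTGCCAGCACC
>TRBV-T04|V|48
GGTGGATTTGGCAATTTCAGTTCGGTACTCAAGATATCATTTCTTCTGTGTGCCAGCGGC
>TRBV-T05|V|48
ACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGGTGTAGCGTGGAG
>TRBV-T06|V|48
CCTGGTACTCTCCGTGGCCTCACGAGGACGCTTACTGCGCCGATCCGCTGTGCCTGGAGC
>TRBV-T07|V|48
CTTACTTCACCATGCCTCTATCGAGCCTATCTGATTGACACTGCCGACTGTGCCAGCCAG
>TRBV-T08|V|48
CATTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAATGTGCCACCAGC
>TRBJ-T01|J|9
AATGAGCAGTTTGTTAAGTCTCAGACCCACGATACCTTGGGGATTGTA
>TRBJ-T02|J|9
ACCCAGTACTTTTTATCAAATCCAATTCTCGTACAACTCTTTGCCTTC
>TRBJ-T03|J|9
GGCTACACCTTTTCGGTCCTGAAATACAGTTCTGTACTTCATGTACCG
>TRBJ-T04|J|9
CCGCAGCACTGGTAGAGTCATTATGTACAACTTTCTTAGCGTGGTCAC
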