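>synthetic-mir-01
TGATATGTAAACTAGCTCAAAT
>synthetic-mir-02
GGTGGTGTGATATGAAGTCAA
>synthetic-mir-03
GCTTGAGTCTTAGAGCAAGGA
>synthetic-mir-04
AGTGTCTTAACAGTGCTCTGA
>synthetic-mir-05
GACGCGTGTGTGATTACATCAT
>synthetic-mir-06
ACTAGCGCGGGTTGTAAATGT
>synthetic-mir-07
TGACCGGCCCTCAGAGGAGTA
>synthetic-mir-08
GGGCTCCCAGGACAGCTCAGCG
>synthetic-mir-09
GCAATGGGGACGCTCCTGGAACT
>synthetic-mir-10
CACAGCTCGTCGAATAACAGTAG
>synthetic-mir-11
CAATACTTTCATCGAGTTGTGCA
>synthetic-mir-12
GTGAGAGGGATGTTAGGAATGG
>synthetic-mir-13
GTTGTGATTATCTCGATTTCGGC
>synthetic-mir-14
CGCCGAGTGCCAGGGCCAATAC
>synthetic-mir-15
TAAAACCGGATTAGGAAAGTTAG
>synthetic-mir-16
GTCAATGCCATTGTTTCCTTGG
>synthetic-mir-17
TTGTGCGACCACCTTGGATACAC
>synthetic-mir-18
CCTCAGACCCGTCTCTTGTCG
>synthetic-mir-19
CCAAATTCGACCTATACGAGCGT
>synthetic-mir-20
CTGGGCTGTAGCGCCTTAGACG
>synthetic-mir-21
AAGATAACAAGAGAGACAGTAC
>synthetic-mir-22
AGTCGGGCAGGTATAAAAAGT
>synthetic-mir-23
GAGCCGCTCCTAAGGGGCCTAGG
>synthetic-mir-24
CTAATATTCTGTTTAGGGTACA
>synthetic-mir-25
ATTGTGACTGATTGATACAGGTC
>synthetic-mir-26
ATCGGTCCATCGGCTGCTTAA
>synthetic-mir-27
TGGCTAAAGAGCCTCAGCCGAG
>synthetic-mir-28
TGCTCTTCAAAATAATGGTCGC
>synthetic-mir-29
AATAGAAGGAATAGTGAAAGTTA
>synthetic-mir-30
TCCCTGGCCTTTTGGACGCGAA
>synthetic-mir-31
AAACACGTGGCGACGGGCCGCCC
>synthetic-mir-32
GATCGCAGCCCGGGGGGGGACG
>synthetic-mir-33
AAAACCTGGAGCGGTCTGTGGC
>synthetic-mir-34
GAGCGTCTCTTCTTCTTGGAC
>synthetic-mir-35
TGGAACTACAAGGGCTAACGATC
>synthetic-mir-36
CCCACCACAGGGACAGGTCGCCA
>synthetic-mir-37
AGTTTAGGCGGCCACTTCCATCG
>synthetic-mir-38
ATCTACTCGATGCTCTATTAGT
>synthetic-mir-39
ACGTTCGTTTGGCCAGGAGCAA
>synthetic-mir-40
CGGCAAATAGCCTCGCACGGCTA
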