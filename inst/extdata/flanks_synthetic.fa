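>left synthetic seed-fixed flank
GCGTTCACGACACTGGCCGAGAGGGCTGAAACTTATATTCCCTACATTGTCGCCCCATGT
GGACGTGACGCCGTCAAGAGCAATCGAGCATTAAGGACGTAAATAGTGGACCGGTGATTA
TCGTGGGTCGGGTTTATGTGGTCTCCTGCCCTGAATTTGCGAGGTCGCTTCTCGTTTACG
AAGGTGGAAGTAAAAACCAGCCCAATTAATGAAAATTAGAAAAGTAAACTGATTAGGAGA
ACGAAGTTAGCGCCATTCTATGATCACCACCCGCACTCATAGCCAGGGCTTGGTTACACT
>right synthetic seed-fixed flank
TAGGGATCCCGTGGGACGCCGTTGCGGTGGTCCGTGGTCCTCCTATAAATGCGGAAAAGC
GACTCCCGACATGATCGCGGTATACTAGATACCCGTGGCGCAGGTAGTGGGTCGAATCAA
CCTGGCGAGTATTTGCTCGTGATTACAAGAGACCGATGGCTTATGTAAATTTGCAGAATT
CAAGGCCTAATGTCGTTTCTTTTGAGGATTACTACACCCCCGCATGCCAGGGAAACGGTA
GATGTGCGCCGGACGGTAGCCGCGGTAATCAACTCGAACCTAAACAGGTAGCAGTCGGTA
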