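>u6_promoter
GCAGCTTGTAAGCTGATGTATTGTCTCCGGATGTTACTACAAGGCCCCGTCCCCTGCTGTGACGCTGGCACCCTTGGGAA
AACCTCTCGTGACGCTGTCTCGTCGGTTCTTTGGTTGGCAAAGCACAGCAATCGCGATAGGAGAGGTAATGAATAGTTAT
TCACGTGGATTCACTACGACCCTTCCTGGGCGAGGTTGGGCCAGCAGGAGCCAGCCGTTCAAATGAATCTGAAATACGTA
CTTAAGATGTGTCAGAGGATAGAGG
>scaffold_terminator
CAAATAACTTGCTTATATCAGTTACGGGAAACATCTGCGCCAGCGAGAGAAGGCATCAACATGACGAGTGCGACGAAACT
CCAAGTCGGTACCAATGTTAACTCTGGACCGAAATAGGTCAA
>vector_flank_up
AGATCTATAGCCACAGTCCTACAGAACCCCGCATAGACACGGCGGAGTCGGCATGACTTCGCTCAATGGACCAAAATGAA
TGTTTTACCTATGCATTGGCCGGGTTAAATCCCTGCCCCGGGGCCCCTTAGCCCAGACATCCCAAAACATGGTTCTTTCG
CTTTTCAGCGAACGCGGTCGTCCGTTCTTGGCATTATCTA
>vector_flank_down
ATTTTTGTTTTCGGTGTATCCCAACACGGAGGGCTTGATCCGCCAGGTTTCTGACCAGGTTCTCACTGAAGCTCACGTTC
TACTAGTTTATTGCAAAGTGGTTCAGCGTCTGTAGGCCCCCGCGCCAAGACAGACCAATGGCCCGATTGCATAACAGGAG
ATGTGGTTGTAGCGGGGGGCCGCACGACGCCCGGAACTGC
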