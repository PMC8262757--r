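>toylib_001
TCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAGTACTTCCCTGTGACCGGTTTAAGTCTTTGCCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATGGACCTCCGGCTCCTAACACTAGAATAAGTATGCGCTCCACACCTGA
>toylib_002
GCACCTCCAGTCCTGTACACAACACCAGGACTCTCACGCGAGGCTTGAAGACCGTCCAGCGATTTGAACCCAGATATAAGTCACTCATTCTAATGAGGCCGAGATCGCCATAGTGAGTGTCAAATGCATGGTTCGTCGGTCGGTACGCTGAGCTATTAGACACTTAAAGAAAATATAGAAAAGCGTGCTTAGGCTAGTATAG
>toylib_003
ACTGGGAACTTAAATGTGGCACACCTCGTGATTGTCAAGTGGCCCATCCGCCCCGCAGCGGGCCTTATAATCATGTTATGTCCTTAAATTCGGACGGCGCGGTACAGCTAGGAGTTGACCCTCTAAGTTAGACCCCTCAAACAGGGGAAGCTGAGTGAAAAATAACTTAGACGACAGAA
>toylib_004
GCCTCGTCTTGTAGTCGAGGCGTCATCCGATAACGCCTGACATAGGAACCGTTAAGCTTATCCGGGCCAATAACTGTTTAATCGAGATAAGCCCCAGGTTAGGTCTCAAGGATCTTTACATGAACTATACCTTTCTTGGAAGCTGGTCTAGAGGCGCCAAAGGCACTCTCTCACAACCAGTCACTGGTTTGGTAAATACACCCCGCTGACATACTACTTCCTGGGCGCCGTTCTATTCCTTTGGTAGGCTGTAACACGTTATCTATTGCCGGACTGACCGATCTCGTCTCGTACCACAT
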