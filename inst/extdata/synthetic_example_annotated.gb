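LOCUS       synthetic_example 875 bp    DNA     circular SYN 21-SEP-2026
DEFINITION  annotated with plasmidann
FEATURES             Location/Qualifiers
     CDS             484..685
                     /label="orfB"
                     /database="toylib"
                     /identity="100.0"
                     /match_coverage="100.0"
                     /fragment="false"
                     /note="synthetic toy open reading frame"
     promoter        237..399
                     /label="promA"
                     /database="toylib"
                     /identity="100.0"
                     /match_coverage="100.0"
                     /fragment="false"
                     /note="synthetic toy promoter"
     terminator      complement(join(794..875,1..83))
                     /label="termD"
                     /database="toylib"
                     /identity="100.0"
                     /match_coverage="55.2"
                     /fragment="true"
                     /note="synthetic toy terminator"
ORIGIN
        1 gattaaacag ttattggccc ggataagctt aacggttcct atgtcaggcg ttatcggatg
       61 acgcctcgac tacaagacga ggcgagaccc acgacgcgac gagaccattt acgattgaaa
      121 tcttcgtttg tttttcgcca agtctagacc ctagctgacc cgtgatcagt tcgacattaa
      181 atcttcgtct gctcataaga gggctgggcg cggataaatg tgttcgatgt aacctgtcgg
      241 attccagacg gcagataaac gactggaacc tttcggggga agagtacttc cctgtgaccg
      301 gtttaagtct ttgcctaatt tagccaagga caatcggtgc gcactttctg atggacctcc
      361 ggctcctaac actagaataa gtatgcgctc cacacctgac tcagcaatgc tggagcggca
      421 cggaccacat gcattgttag agcaacaggc caagttcacg cggtagcgat agacgcgtcg
      481 cgtgcacctc cagtcctgta cacaacacca ggactctcac gcgaggcttg aagaccgtcc
      541 agcgatttga acccagatat aagtcactca ttctaatgag gccgagatcg ccatagtgag
      601 tgtcaaatgc atggttcgtc ggtcggtacg ctgagctatt agacacttaa agaaaatata
      661 gaaaagcgtg cttaggctag tatagatcac ggagtactcg caaatgaagg gcattccctg
      721 tatcttcggc aaatatatat aaggtcggag gtagaatcct agtgtagaga ggccggcgga
      781 aaaccacttt ctctgccttt ggcgcctcta gaccagcttc caagaaaggt atagttcatg
      841 taaagatcct tgagacctaa cctggggctt atctc
//
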