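LOCUS       SYNTOY01             900 bp    DNA     circular INV
DEFINITION  synthetic toy mitogenome fragment (generated fixture).
FEATURES             Location/Qualifiers
     CDS             50..235
                     /gene="COI"
     tRNA            complement(300..365)
                     /product="tRNA-Leu(UAA)"
     rRNA            420..760
                     /product="12S ribosomal RNA"
     CDS             join(851..900,1..40)
                     /gene="ND3"
ORIGIN
        1 actgtttatt gcaagaagct aagttagatt agaatcgttt ctatcgtgca tgcaatatga
       61 acccgctaca ccccagggtt cgctgccccc tttgctcctc tcgtcgtcac cagatttcat
      121 cttacgtgtt gtggctaaga tagtgcctaa catcgccgtt atcgctaggt cttcgaataa
      181 aggaatggag aagagtttcg catatcagtt attttttctt gttattaggt actaattgga
      241 aaacttaccg taaagacgtt gtttcacaat ttgatattct atgcaaagta agttaaatct
      301 atgcaagggc atgtaagttt ggtccctcag tgactatcta gtctatttct tcgcgtgcat
      361 ctcattggac gtaatacaaa tagtatgaaa ttcgtatact aagcgtaaca gcacctccgt
      421 agctaatgta ctataagata agtttcacgc atttatattt ttctaagatt ttttctatca
      481 tcaaaacatt catttcatta tgatttagtt aagaaccact gttatctaga taaatcctcc
      541 ttacttgacg cgactttcaa tgtttgcatc cccgttgcta agcaagaaat aaatatgtaa
      601 gtatatcgat aaattagaat gttatgggaa attttttcat agattagaca gtcataagtg
      661 ttatcgagat acactggtaa ttcctcccat atgaaaaatt aattactata tcttcttatt
      721 tgtatcttgt cgttaatatt gtaaccgaag ataaataaat acctgattta ttatttgctg
      781 ataagcatcg ctgaatgatt ataacaataa tctttgcttt gtgttagtcc tgaattatct
      841 atggctttaa tttcaagtat cgtataatta acttacgtaa caatattatt catgattcag
//
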