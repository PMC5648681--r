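synthetic microsatellite genotypes (Balding-Nichols, F = 0.12)
Locus1
Locus2
Locus3
Locus4
Pop
Pop1_1 , 005005 004004 003004 005004
Pop1_2 , 005006 003003 003004 005005
Pop1_3 , 005005 005005 003003 001001
Pop1_4 , 005002 005003 004003 001005
Pop1_5 , 005001 003003 003003 005004
Pop1_6 , 006001 004004 003004 005005
Pop1_7 , 002002 005005 003004 005005
Pop1 , 002005 005003 003004 005005
Pop
Pop2_1 , 001005 005001 004003 004004
Pop2_2 , 003001 005005 004003 004005
Pop2_3 , 006001 003003 003001 000000
Pop2_4 , 005005 001001 003001 005006
Pop2_5 , 001001 001003 003005 004006
Pop2_6 , 001001 000000 005001 006006
Pop2_7 , 000000 005003 001003 004006
Pop2 , 001001 005005 001001 005005
Pop
Pop3_1 , 006006 005003 004003 005005
Pop3_2 , 003003 005001 003004 005001
Pop3_3 , 006006 001005 004004 000000
Pop3_4 , 002002 005005 004001 005004
Pop3_5 , 006003 000000 004004 004005
Pop3_6 , 003006 001005 004003 006005
Pop3_7 , 006002 003001 003003 006005
Pop3 , 006005 005005 004004 004001
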