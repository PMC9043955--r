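>ref_SVA
AAGATTCAAGTCAAGAGGACCCATCCCCGCAGCCTCCTTCGAACGCTAGATCGTATCGAACCGGGGGTGGCTCAAAAGATTCCGGCTCCACTTGGAAGTACCCCCGAACAGCGGGGCCCCCAGTTCAGGTTGTGCCGGTCTATAGGTTTGCCGACTGGGGCGGTATAAAACCGAGGGTCGTGTTAAGCCATACTCACAGAGCGCACGCGCCCGGTTAT--TATCAGATTC
>ref_SVB
AAGATTCAAGTCAAGAGGACCCATCTCCGCAGCCTCCTTCGAACGCTAGAACGTATCGAACCGGGGGTGGCTCAAAAGATTCCGGCTCCACTTGGAAGTACCCCCGAACAGCGGGGCCC------------GTGCCCGTCTATAGGTTTGCCGACTGGGGCGGTATAAAACCGAGGGTCGTGTTTAGCCATACTCACAGAGCGCACGCGCCCGGTTAT--TATCAGATTC
>ref_SVC
AAGATTCAAGTCAAGAGGACCCACCCCCGCAGCCCCCTTCGAACGCTAGATCGTATCGA----------------AAGATTCCGGCTCCACTTGGAAGTACCCCCGAACAGCGGGGCCCCCAGTTCAGGTTGTGCAGGTCTATAGGATTGCCGACTGGGGCGGTATAAAACCGAGGGTCGTGTTAAGCCATACTCACAGAGCGCACGCGCCCGGTTAT--TATCAGATTC
>ref_SVD
AAGACTCAAGTCAAGCGGATCCATCCCCGCAGCCTCCTTCGAACGCTAGATCGTATCGA----------------AAGATTCCGGCTGCACTTGGAAGTACCCCCGAACAGCGGGGCCCCCAGTTCAGGTTGTGCCGGTCTATAGGTTTGCCGACTGGGGCGGTATAAAACCGAGGGTGGTGTTAATCCATACTCACAGAGCGGACGCGCCCGGTTATGCTATCAGATTC
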