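name,forward,reverse,expected_amplicon_bp
H. variegata,CTGATATAGCATTCCCTCGTCTT,GTTCCAGCCCCTATTTCAACA,104
C. septempunctata,CCCACCTGCCTTAACCTTACTT,GGCCCATTATGAGCTAAGTTAGAG,108
A. gossypii,GGTATTTGATCAGGTATAATTGGT,ATTAATGAGGGTGGTAATAATCAG,263
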