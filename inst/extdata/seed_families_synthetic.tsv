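family	seed	node
MIR-10	ACCCTGT	Eumetazoa
LET-7	GAGGTAG	Bilateria
MIR-1	GGAATGT	Bilateria
MIR-7	GGAAGAC	Bilateria
MIR-8	TAGAATA	Bilateria
MIR-9	CTTTGGT	Bilateria
MIR-22	GGCTTTA	Bilateria
MIR-29	TTACAGT	Bilateria
MIR-31	CTGATGA	Bilateria
MIR-33	AAAAGGA	Bilateria
MIR-34	GGCAGTG	Bilateria
MIR-46	GATTTTC	Bilateria
MIR-71	GCCGACC	Bilateria
MIR-76	CGTGTCG	Bilateria
MIR-79	ACTACTC	Bilateria
MIR-92	AATAAAG	Bilateria
MIR-96	GCCTGTA	Bilateria
MIR-124	AAGGCAC	Bilateria
MIR-125	TAATACA	Bilateria
MIR-133	TACCGGT	Bilateria
MIR-137	ATCCAAT	Bilateria
MIR-153	GCACAAA	Bilateria
MIR-182	GTTGTTA	Bilateria
MIR-184	CTAATTT	Bilateria
MIR-190	CGCCTCC	Bilateria
MIR-193	TGGTAGA	Bilateria
MIR-210	TGGTCTG	Bilateria
MIR-216	AGAAACG	Bilateria
MIR-219	TAATACC	Bilateria
MIR-252	CGTGTTC	Bilateria
MIR-278	GAGGGAG	Bilateria
MIR-281	GTCCTTC	Bilateria
BANTAM	GAGATCA	Protostomia
MIR-2	ATCACAG	Protostomia
MIR-12	AAAAAAC	Protostomia
MIR-87	ACTTGAG	Protostomia
MIR-277	AGTCGAA	Protostomia
MIR-279	GAGCTTC	Protostomia
MIR-317	CCTTACT	Protostomia
MIR-750	AGTCTAC	Protostomia
MIR-981	GAATTTA	Protostomia
MIR-1175	AATTATT	Protostomia
MIR-1993	TTCCCAA	Protostomia
MIR-1989	ACAGATA	Spiralia
MIR-1992	ATCGTAC	Spiralia
MIR-305	AAGGAAA	Ecdysozoa
MIR-54	TGAGCCT	Nematoda
MIR-86	GGGAGTG	Nematoda
MIR-791	CAGTACT	Nematoda
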