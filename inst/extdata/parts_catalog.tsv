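name	role	sequence	source
O_1	proximal_op	AATTGTGAGCGGATAACAATT	native lac operator O1
O_1	distal_op	AATTGTGAGCGGATAACAATT	native lac operator O1
O_2-var	proximal_op	AATTGTGAGCGAGTAACAACT	synthetic 3-mutation variant of native O2
O_2-var	distal_op	AATTGTGAGCGAGTAACAACT	synthetic 3-mutation variant of native O2
O_3	proximal_op	GGCAGTGAGCGCAACGCAATT	native lac operator O3
O_3	distal_op	GGCAGTGAGCGCAACGCAATT	native lac operator O3
O_sym	proximal_op	AATTGTGAGCGGCTCACAATT	palindrome of O1 left half-site
O_sym	distal_op	AATTGTGAGCGGCTCACAATT	palindrome of O1 left half-site
O_scram	proximal_op	TCAAGCGGATAAATTGAATTG	seeded composition-preserving scramble of O1 (negative control)
O_scram	distal_op	TCAAGCGGATAAATTGAATTG	seeded composition-preserving scramble of O1 (negative control)
O_1:R-sym	proximal_op	AATTGTTATCGGATAACAATT	palindrome of O1 right half-site
O_1:R-sym	distal_op	AATTGTTATCGGATAACAATT	palindrome of O1 right half-site
O_2:L-sym	proximal_op	AAATGTGAGCGGCTCACATTT	palindrome of O2 left half-site
O_2:L-sym	distal_op	AAATGTGAGCGGCTCACATTT	palindrome of O2 left half-site
O_2:R-sym	proximal_op	GGTTGTTACTGAGTAACAACC	palindrome of O2 right half-site
O_2:R-sym	distal_op	GGTTGTTACTGAGTAACAACC	palindrome of O2 right half-site
O_3:L-sym	proximal_op	GGCAGTGAGCGGCTCACTGCC	palindrome of O3 left half-site
O_3:L-sym	distal_op	GGCAGTGAGCGGCTCACTGCC	palindrome of O3 left half-site
O_3:R-sym	proximal_op	AATTGCGTTGGCAACGCAATT	palindrome of O3 right half-site
O_3:R-sym	distal_op	AATTGCGTTGGCAACGCAATT	palindrome of O3 right half-site
O_1	distalplus_op	AATTGTGAGCGGATAACAATT	native lac operator O1
O_1	core_op	AATTGTGAGCGGATAACAATT	native lac operator O1
O_1	spacer_op	TTGTGAGCGGATAACAA	native lac operator O1 (trimmed 2 bp each end)
O_2-var	distalplus_op	AATTGTGAGCGAGTAACAACT	synthetic 3-mutation variant of native O2
O_2-var	core_op	AATTGTGAGCGAGTAACAACT	synthetic 3-mutation variant of native O2
O_2-var	spacer_op	TTGTGAGCGAGTAACAA	synthetic 3-mutation variant of native O2 (trimmed 2 bp each end)
O_3	distalplus_op	GGCAGTGAGCGCAACGCAATT	native lac operator O3
O_3	core_op	GGCAGTGAGCGCAACGCAATT	native lac operator O3
O_3	spacer_op	CAGTGAGCGCAACGCAA	native lac operator O3 (trimmed 2 bp each end)
O_sym	distalplus_op	AATTGTGAGCGGCTCACAATT	palindrome of O1 left half-site
O_sym	core_op	AATTGTGAGCGGCTCACAATT	palindrome of O1 left half-site
O_sym	spacer_op	TTGTGAGCGGCTCACAA	palindrome of O1 left half-site (trimmed 2 bp each end)
O_scram	distalplus_op	TCAAGCGGATAAATTGAATTG	seeded composition-preserving scramble of O1 (negative control)
O_scram	core_op	TCAAGCGGATAAATTGAATTG	seeded composition-preserving scramble of O1 (negative control)
O_scram	spacer_op	AAGCGGATAAATTGAAT	seeded composition-preserving scramble of O1 (negative control) (trimmed 2 bp each end)
TATAAT	minus10	TATAAT	sigma70 consensus -10
TATGTT	minus10	TATGTT	weakened -10 variant
TACACT	minus10	TACACT	weakened -10 variant
CATAAT	minus10	CATAAT	weakened -10 variant
TTGACA	minus35	TTGACA	sigma70 consensus -35
TTTACA	minus35	TTTACA	weakened -35 variant
TTGATT	minus35	TTGATT	weakened -35 variant
TCGACC	minus35	TCGACC	weakened -35 variant
UP_1	up_element	TAAATTATTAAAAAAT	synthetic AT-rich UP element stand-in
UP_2	up_element	AATTAAATATTTAATA	synthetic AT-rich UP element stand-in
UP_3	up_element	ATTTTTATATAAAAAT	synthetic AT-rich UP element stand-in
UP_4	up_element	ATATTAATTATTTTTA	synthetic AT-rich UP element stand-in
TGG	ext10	TGG	most common extended -10 motif
LacI_prox	proximal_op	AAAACTCCATGTGTAACTCCGGA	synthetic 23 bp TF operator stand-in
LacI_dist	distal_op	AGTAGAATCTTGCACTCGGCCTT	synthetic 23 bp TF operator stand-in
AraC_prox	proximal_op	TCCATATCTCGTGAACCCCCTGC	synthetic 23 bp TF operator stand-in
AraC_dist	distal_op	ACGCCCTAAAGTACAATTAGGAT	synthetic 23 bp TF operator stand-in
GalR_prox	proximal_op	ATTCATCCCTACACTGTATATGC	synthetic 23 bp TF operator stand-in
GalR_dist	distal_op	CGAACGTTCTAATAAACGACTTA	synthetic 23 bp TF operator stand-in
GlpR_prox	proximal_op	GCAACAAGTCGCCTAGAAAGGTA	synthetic 23 bp TF operator stand-in
GlpR_dist	distal_op	CCGCTGGCATATCACGCCTCCCG	synthetic 23 bp TF operator stand-in
LldR_prox	proximal_op	CTTGCCGTCTTCAACTTCATGAC	synthetic 23 bp TF operator stand-in
LldR_dist	distal_op	CCTCGTGCATCACAAAGCCTCAA	synthetic 23 bp TF operator stand-in
PurR_prox	proximal_op	GCCGGAGTCTAGGCTTTGAAACA	synthetic 23 bp TF operator stand-in
PurR_dist	distal_op	GCTGAATAAATCGTGTGAATACG	synthetic 23 bp TF operator stand-in
lacUV5_backbone	backbone	CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAGCTTATCGTCCCTGTCGATCGAATTCGTTTCCTACCTTTACAATCTCTTAGATGTGCAATATAATACATAGACTCGTTATCTTACGCAGCAGGGCGTCCTAAATATGCGTGAGCTCTACTA	synthetic lacUV5-like backbone, -130..+50, L8/L29-insensitive surrogate
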