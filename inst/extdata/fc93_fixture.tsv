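# FC93: deterministic 93-subject synthetic genotype fixture.
# Joint genotypes are DERIVED, not published: the published cohort reports
# only per-SNP genotype marginals and haplotype-call counts (50 H1H1, 1 H1H2,
# 1 unique H1H7, 31 ambiguous H1H7-or-H1H9, 1 unique H1H9, 8 H7H7, 1 H8H9).
# This table is the unique joint assignment compatible with the default
# haplotype matrix that reproduces those haplotype counts and the printed
# 381/5808/9041 marginals exactly. The 861 marginal (here 92/0/1) cannot
# simultaneously match the printed 91/0/2 row: the haplotype column admits at
# most one 861 hom-mut subject. This is a documented inconsistency in the
# source tables, carried as-is rather than silently patched.
# pair: the generating haplotype pair; fills: wildcard instantiations used,
# as "hap:site=base" pairs separated by ";".
snp381	snp861	snp5808	snp9041	count	pair	fills
C/C	C/C	T/T	G/G	50	H1H1	H1:9041=G
C/C	C/C	G/T	A/G	1	H1H2	H1:9041=A;H2:9041=G
C/T	C/C	T/T	A/A	1	H1H7	H1:9041=A
C/T	C/C	T/T	A/G	31	H1H7	H1:9041=G
C/T	C/C	T/T	G/G	1	H1H9	H1:9041=G;H9:861=C
T/T	C/C	T/T	A/A	8	H7H7	
T/T	A/A	T/T	A/G	1	H8H9	H9:861=A
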