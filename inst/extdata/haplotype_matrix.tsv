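# Default VKORC1 haplotype definition matrix over the four assay SNPs.
# "*" is a wildcard: the haplotype is unconstrained at that site (the
# haplotyping decision tree never consults that branch for that haplotype).
# H1/H2 are the low warfarin-dose haplotypes, H7/H8/H9 the high-dose ones.
name	a381	a861	a5808	a9041
H1	C	C	T	*
H2	C	C	G	*
H7	T	C	T	A
H8	T	A	T	A
H9	T	*	T	G
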