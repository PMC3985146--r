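# VKORC1 SNP panel used by the nested allele-specific multiplex assay.
# Coordinates are 1-based on the surrogate reference; hgvs_position is the
# alternative published coordinate system (offset -85 from position).
# Alleles are plus-strand; wt = wild type, mut = mutant.
id	position	hgvs_position	wt_allele	mut_allele
381	381	296	C	T
861	861	776	C	A
5808	5808	5723	T	G
9041	9041	8956	G	A
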