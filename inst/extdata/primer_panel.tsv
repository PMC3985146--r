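# Primer panel for the two-round nested allele-specific multiplex VKORC1 assay.
# round: PCR1 (outer, common primers) or PCR2 (inner, allele-specific + common).
# role: common | wt_specific | mut_specific; snp_id set for allele-specific rows.
# footprint_start/footprint_end: 1-based inclusive plus-strand coordinates
# (minus-strand primers are printed 5'->3', footprint stored ascending).
# product_size: expected amplicon size in bp for the pair the row belongs to.
# reported_tm: melting temperature in Celsius (metadata only).
name	round	target	role	snp_id	sequence	strand	footprint_start	footprint_end	length	product_size	reported_tm
381&861 Com (F)	PCR1	381&861	common	NA	GCCCAGGAGTTAGAGGCAACATAAC	plus	257	281	25	1060	66.2
381&861 Com (R)	PCR1	381&861	common	NA	CAGCTTTCTCTGATCTCCTGGTGTG	minus	1292	1316	25	1060	66.2
5808 Com (F)	PCR1	5808	common	NA	ATTCTGGAGTCTGGGATCGGTGTG	plus	5546	5569	24	398	66.3
5808 Com (R)	PCR1	5808	common	NA	ACCCCAGAATCTCCAGCTCCCTG	minus	5921	5943	23	398	68.1
9041 Com (F)	PCR1	9041	common	NA	CAGCTCCTGGCATCTAGGTAGTGC	plus	8604	8627	24	853	68.0
9041 Com (R)	PCR1	9041	common	NA	CTTCCAGGTGTGTGCTCAGCCTTC	minus	9433	9456	24	853	68.0
381&861 Com (R) PCR2	PCR2	381&861	common	NA	CAGCTTTCTCTGATCTCCTGGTGTG	minus	1292	1316	25	NA	66.2
381 WT (F)	PCR2	381	wt_specific	381	AGCACTTTAGGAAGCCAAGGAGGGC	plus	357	381	25	960	67.9
381 Mut (F)	PCR2	381	mut_specific	381	AGCACTTTAGGAAGCCAAGGAGGGT	plus	357	381	25	960	66.2
861 WT (F)	PCR2	861	wt_specific	861	AAACTCCTGACCTCAGGTGATCCAC	plus	837	861	25	480	66.2
861 Mut (F)	PCR2	861	mut_specific	861	AAACTCCTGACCTCAGGTGATCCAA	plus	837	861	25	480	64.6
5808 Com (F) PCR2	PCR2	5808	common	NA	ATTCTGGAGTCTGGGATCGGTGTG	plus	5546	5569	24	NA	66.3
5808 WT (R)	PCR2	5808	wt_specific	5808	CGCCAACACCCCCCTTCA	minus	5808	5825	18	280	71.7
5808 Mut (R)	PCR2	5808	mut_specific	5808	CGCCAACACCCCCCTTCC	minus	5808	5825	18	280	70.8
9041 Com (R) PCR2	PCR2	9041	common	NA	CTTCCAGGTGTGTGCTCAGCCTTC	minus	9433	9456	24	NA	68.0
9041 WT (F)	PCR2	9041	wt_specific	9041	CCTCCTCCTGCCATACCCG	plus	9023	9041	19	434	66.6
9041 Mut (F)	PCR2	9041	mut_specific	9041	CCTCCTCCTGCCATACCCA	plus	9023	9041	19	434	64.5
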