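star_allele	suballele	structural_kind	core_variants	sub_variants
*1	*1.001	NONE		
*1	*1.037	NONE		31650:G>A
*1	*1.045	NONE		32100:T>C
*1	*1.058	NONE		30220:A>G
*1	*1.059	NONE		33900:T>C
*2	*2.001	NONE	29650:A>G;31200:A>G	29650:A>G;31200:A>G
*2	*2.033	NONE	29650:A>G;31200:A>G	29650:A>G;31200:A>G;33500:T>C
*4	*4.001	NONE	29900:G>A	29900:G>A
*10	*10.001	NONE	29750:T>C	29750:T>C
*29	*29.001	NONE	30500:C>T;32800:A>G	30500:C>T;32800:A>G
*5	*5.001	DELETION		
*36	*36	HYBRID_TANDEM		
*68	*68	HYBRID_TANDEM		
*13	*13	HYBRID_TANDEM		
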