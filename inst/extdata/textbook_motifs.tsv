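# Example kinase recognition motifs for testing and demonstration only.
# These are common textbook consensus patterns, NOT an authoritative or
# curated kinase-substrate resource.
# name<TAB>pattern   (grammar: see ?parse_motif)
CDK_proline_directed	pS/pT-P
MAPK_proline_directed	P-X-pS/pT-P
PKA_basophilic	R-R-X-pS/pT
PKC_basophilic	pS/pT-X-R/K
CK1_acidophilic	pS/pT-X-X-[ST]
CK2_acidophilic	pS/pT-X-X-[DE]
GSK3_primed	pS/pT-X-X-X-[ST]
CAMK2	R-X-X-pS/pT
AKT_RxRxxST	R-X-R-X-X-pS/pT
ATM_SQ	pS/pT-Q
SRC_tyrosine	[DE]-X-X-pY
ABL_tyrosine	pY-X-X-P
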