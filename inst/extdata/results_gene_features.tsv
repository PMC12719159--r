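gene_symbol	pli	oe_lof	tissue_class	druggable_any
AR	0.27	0.53	tissue_enhanced	TRUE
ATN1	0.98	0.13	low_tissue_specificity	FALSE
ATXN1	1	0.05	low_tissue_specificity	TRUE
ATXN2	0.54	0.42	low_tissue_specificity	TRUE
ATXN3	0.09	0.74	low_tissue_specificity	FALSE
ATXN7	0.97	0.18	low_tissue_specificity	FALSE
CACNA1A	1	0.07	tissue_enriched	TRUE
HTT	1	0.1	low_tissue_specificity	TRUE
TBP	0.88	0.35	low_tissue_specificity	FALSE
THAP11	0.62	0.48	low_tissue_specificity	FALSE
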