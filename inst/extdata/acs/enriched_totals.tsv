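# Total number of significantly enriched pathways per ACS subtype
# (hypergeometric p < 0.05 and FDR < 0.05).
condition	n_enriched
AMI	35
UA	18
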