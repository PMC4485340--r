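#title	CoXpress: differential co-expression in gene expression data
We ran BLAST against the UniProt records. The Gene Ontology annotations were retrieved with Bioconductor. BLAST performed well.
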