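canonical	rtype	source	variants
BLAST	SW	demo	BLAST
UniProt	DB	demo	UniProt|Uniprot
Gene Ontology	DB	demo	Gene Ontology|GO
SCOP	DB	demo	SCOP
Bioconductor	PK	demo	Bioconductor
MySQL	SW	demo	MySQL
ClustalW	SW	demo	ClustalW|CLUSTALW|CLUSTAL W
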