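barcode_id	sequence
BC01	AGAAGAAT
BC02	CCAACTGT
BC03	GAGTTAAC
BC04	TGCAGGAC
BC05	TCCAATTC
BC06	AAGCGAGA
BC07	CCGCGCCC
BC08	TCGACCTA
BC09	TTTTTGTC
BC10	ATCGATGG
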