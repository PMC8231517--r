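barcode	total_reads	mapped_reads	n_genes
barcode1	1293001	878970	10869
barcode2	2029051	1382710	12006
barcode3	1401956	909050	10917
barcode4	2640182	1331922	11690
barcode5	1871851	784207	11442
barcode6	1196100	821091	10418
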