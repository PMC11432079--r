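# Isoform grouping for the human THRA locus: variants ending in the
# read-through exon 9b form THRA1, variants ending in exon 10 form THRA2.
gene_id: ENSG00000126351
groups:
  THRA1:
    - ENST00000450525
    - ENST0000054624
  THRA2:
    - ENST00000264637
    - ENST00000584985
min_length: 100
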