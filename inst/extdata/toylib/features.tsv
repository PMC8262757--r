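# library_tag: toylib
# alphabet: nucleotide
# search_kind: nucleotide
# evalue_cutoff: 1
# identity_cutoff: 98
entry_id	name	type_key	description	annotation_score
toylib_001	promA	promoter	synthetic toy promoter	NA
toylib_002	orfB	CDS	synthetic toy open reading frame	NA
toylib_003	oriC	rep_origin	synthetic toy replication origin	NA
toylib_004	termD	terminator	synthetic toy terminator	NA
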