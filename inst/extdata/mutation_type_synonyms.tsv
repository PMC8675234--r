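raw_label	canonical
truncating_snv	TruncatingSNV
truncating	TruncatingSNV
nonsense	TruncatingSNV
nonsense_mutation	TruncatingSNV
stop_gained	TruncatingSNV
stopgain	TruncatingSNV
translation_start_site	TruncatingSNV
splice_site_snv	SpliceSiteSNV
splice_site	SpliceSiteSNV
splice_site_variant	SpliceSiteSNV
splice_region	SpliceSiteSNV
splicing	SpliceSiteSNV
splice_site_mutation	SpliceSiteSNV
missense_snv	MissenseSNV
missense	MissenseSNV
missense_mutation	MissenseSNV
missense_variant	MissenseSNV
nonstop_mutation	MissenseSNV
indel	Indel
frame_shift_del	Indel
frame_shift_ins	Indel
in_frame_del	Indel
in_frame_ins	Indel
frameshift	Indel
frameshift_variant	Indel
inframe_insertion	Indel
inframe_deletion	Indel
insertion	Indel
deletion	Indel
insert_or_delete	Indel
synonymous_snv	SynonymousSNV
synonymous	SynonymousSNV
synonymous_variant	SynonymousSNV
silent	SynonymousSNV
multiple_types	MultipleTypes
multiple	MultipleTypes
multi_hit	MultipleTypes
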