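transcript_id	has_homology_hit	has_domain_hit	curation_status
g1.t1	TRUE	FALSE	Annotated
g1.t2	FALSE	FALSE	Mapped
g2.t1	FALSE	TRUE	Mapped
g2.t2	TRUE	TRUE	NoHit
g3.t1	TRUE	TRUE	Annotated
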