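# source_id	target_id
1001	ENSGTEST00000001
2004	ENSGTEST00000003
2005	ENSGTEST00000004
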