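id	logFC	p_value	adj_p_value
ENSGTEST00000001	-0.388780604216853	0.436827737204386	0.436827737204386
ENSGTEST00000002	-2.21649810874976	9.2932497068604e-06	1.85864994137208e-05
ENSGTEST00000003	1.22012513098598	0.014677090187958	0.019569453583944
ENSGTEST00000004	2.86801395398241	9.69226976960913e-09	3.87690790784365e-08
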