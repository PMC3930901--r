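seq_id	n_ssr	poly_dqj	poly_n10	designed	polymorphic_markers
Chr.1	607	108	215	72	67
Chr.2	612	121	238	86	85
Chr.3	542	159	204	90	85
Chr.4	396	82	157	65	62
Chr.5	604	158	268	90	88
Chr.6	568	158	261	123	110
Chr.7	372	86	173	94	86
Chr.8	493	153	187	35	34
Chr.9	826	194	350	133	116
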