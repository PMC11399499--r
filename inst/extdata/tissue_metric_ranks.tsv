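tissue	out_degree	closeness	betweenness	go	borda
flower	4	2	1	5	3
leaf	4	3	2	5	1
root	3	4	5	1	2
seed	5	1	3	4	2
seedling	5	1	2	4	3
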