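Rank	Name	Score
1	TIMP1	10
2	SERPINE1	8
3	APOB	7
4	IL1R2	5
4	IL10RA	5
6	CTLA4	4
6	FGG	4
6	FAM20C	4
6	PCSK9	4
6	ANXA2	4
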