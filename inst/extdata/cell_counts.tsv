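genotype	novel_pyramidal	novel_active	familiar_pyramidal	familiar_active
WT	23	12	36	27
WT	NA	NA	1	1
WT	21	15	8	5
WT	8	6	6	4
WT	10	6	26	11
WT	1	1	7	6
WT	9	4	18	11
WT	12	9	NA	NA
RTT	NA	NA	36	29
RTT	5	5	5	4
RTT	6	5	8	6
RTT	6	5	34	27
RTT	7	3	19	14
RTT	10	8	30	23
RTT	1	1	3	0
RTT	1	1	0	0
RTT	0	0	NA	NA
RTT	3	3	NA	NA
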