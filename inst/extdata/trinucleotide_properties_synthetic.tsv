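tuple	twist_step1	tilt_step1	roll_step1	shift_step1	slide_step1	rise_step1	twist_step2	tilt_step2	roll_step2	shift_step2	slide_step2	rise_step2
AAA	35.6	-1.4	0.7	-0.03	-0.08	3.27	35.6	-1.4	0.7	-0.03	-0.08	3.27
AAC	35.6	-1.4	0.7	-0.03	-0.08	3.27	32.1	-0.1	0.7	0.13	-0.58	3.36
AAG	35.6	-1.4	0.7	-0.03	-0.08	3.27	31.5	-1.7	4.5	0.09	-0.25	3.34
AAT	35.6	-1.4	0.7	-0.03	-0.08	3.27	29.3	0	1.1	0	-0.59	3.31
ACA	32.1	-0.1	0.7	0.13	-0.58	3.36	37.3	0.5	4.7	0.09	0.53	3.33
ACC	32.1	-0.1	0.7	0.13	-0.58	3.36	33.6	-0.1	3.6	0.05	-0.22	3.42
ACG	32.1	-0.1	0.7	0.13	-0.58	3.36	36.1	0	5.4	0	0.41	3.39
ACT	32.1	-0.1	0.7	0.13	-0.58	3.36	31.5	-1.7	4.5	0.09	-0.25	3.34
AGA	31.5	-1.7	4.5	0.09	-0.25	3.34	39.3	-1.5	1.9	-0.28	0.09	3.37
AGC	31.5	-1.7	4.5	0.09	-0.25	3.34	38.3	0	0.3	0	-0.38	3.4
AGG	31.5	-1.7	4.5	0.09	-0.25	3.34	33.6	-0.1	3.6	0.05	-0.22	3.42
AGT	31.5	-1.7	4.5	0.09	-0.25	3.34	32.1	-0.1	0.7	0.13	-0.58	3.36
ATA	29.3	0	1.1	0	-0.59	3.31	37.8	0	3.3	0	0.05	3.42
ATC	29.3	0	1.1	0	-0.59	3.31	39.3	-1.5	1.9	-0.28	0.09	3.37
ATG	29.3	0	1.1	0	-0.59	3.31	37.3	0.5	4.7	0.09	0.53	3.33
ATT	29.3	0	1.1	0	-0.59	3.31	35.6	-1.4	0.7	-0.03	-0.08	3.27
CAA	37.3	0.5	4.7	0.09	0.53	3.33	35.6	-1.4	0.7	-0.03	-0.08	3.27
CAC	37.3	0.5	4.7	0.09	0.53	3.33	32.1	-0.1	0.7	0.13	-0.58	3.36
CAG	37.3	0.5	4.7	0.09	0.53	3.33	31.5	-1.7	4.5	0.09	-0.25	3.34
CAT	37.3	0.5	4.7	0.09	0.53	3.33	29.3	0	1.1	0	-0.59	3.31
CCA	33.6	-0.1	3.6	0.05	-0.22	3.42	37.3	0.5	4.7	0.09	0.53	3.33
CCC	33.6	-0.1	3.6	0.05	-0.22	3.42	33.6	-0.1	3.6	0.05	-0.22	3.42
CCG	33.6	-0.1	3.6	0.05	-0.22	3.42	36.1	0	5.4	0	0.41	3.39
CCT	33.6	-0.1	3.6	0.05	-0.22	3.42	31.5	-1.7	4.5	0.09	-0.25	3.34
CGA	36.1	0	5.4	0	0.41	3.39	39.3	-1.5	1.9	-0.28	0.09	3.37
CGC	36.1	0	5.4	0	0.41	3.39	38.3	0	0.3	0	-0.38	3.4
CGG	36.1	0	5.4	0	0.41	3.39	33.6	-0.1	3.6	0.05	-0.22	3.42
CGT	36.1	0	5.4	0	0.41	3.39	32.1	-0.1	0.7	0.13	-0.58	3.36
CTA	31.5	-1.7	4.5	0.09	-0.25	3.34	37.8	0	3.3	0	0.05	3.42
CTC	31.5	-1.7	4.5	0.09	-0.25	3.34	39.3	-1.5	1.9	-0.28	0.09	3.37
CTG	31.5	-1.7	4.5	0.09	-0.25	3.34	37.3	0.5	4.7	0.09	0.53	3.33
CTT	31.5	-1.7	4.5	0.09	-0.25	3.34	35.6	-1.4	0.7	-0.03	-0.08	3.27
GAA	39.3	-1.5	1.9	-0.28	0.09	3.37	35.6	-1.4	0.7	-0.03	-0.08	3.27
GAC	39.3	-1.5	1.9	-0.28	0.09	3.37	32.1	-0.1	0.7	0.13	-0.58	3.36
GAG	39.3	-1.5	1.9	-0.28	0.09	3.37	31.5	-1.7	4.5	0.09	-0.25	3.34
GAT	39.3	-1.5	1.9	-0.28	0.09	3.37	29.3	0	1.1	0	-0.59	3.31
GCA	38.3	0	0.3	0	-0.38	3.4	37.3	0.5	4.7	0.09	0.53	3.33
GCC	38.3	0	0.3	0	-0.38	3.4	33.6	-0.1	3.6	0.05	-0.22	3.42
GCG	38.3	0	0.3	0	-0.38	3.4	36.1	0	5.4	0	0.41	3.39
GCT	38.3	0	0.3	0	-0.38	3.4	31.5	-1.7	4.5	0.09	-0.25	3.34
GGA	33.6	-0.1	3.6	0.05	-0.22	3.42	39.3	-1.5	1.9	-0.28	0.09	3.37
GGC	33.6	-0.1	3.6	0.05	-0.22	3.42	38.3	0	0.3	0	-0.38	3.4
GGG	33.6	-0.1	3.6	0.05	-0.22	3.42	33.6	-0.1	3.6	0.05	-0.22	3.42
GGT	33.6	-0.1	3.6	0.05	-0.22	3.42	32.1	-0.1	0.7	0.13	-0.58	3.36
GTA	32.1	-0.1	0.7	0.13	-0.58	3.36	37.8	0	3.3	0	0.05	3.42
GTC	32.1	-0.1	0.7	0.13	-0.58	3.36	39.3	-1.5	1.9	-0.28	0.09	3.37
GTG	32.1	-0.1	0.7	0.13	-0.58	3.36	37.3	0.5	4.7	0.09	0.53	3.33
GTT	32.1	-0.1	0.7	0.13	-0.58	3.36	35.6	-1.4	0.7	-0.03	-0.08	3.27
TAA	37.8	0	3.3	0	0.05	3.42	35.6	-1.4	0.7	-0.03	-0.08	3.27
TAC	37.8	0	3.3	0	0.05	3.42	32.1	-0.1	0.7	0.13	-0.58	3.36
TAG	37.8	0	3.3	0	0.05	3.42	31.5	-1.7	4.5	0.09	-0.25	3.34
TAT	37.8	0	3.3	0	0.05	3.42	29.3	0	1.1	0	-0.59	3.31
TCA	39.3	-1.5	1.9	-0.28	0.09	3.37	37.3	0.5	4.7	0.09	0.53	3.33
TCC	39.3	-1.5	1.9	-0.28	0.09	3.37	33.6	-0.1	3.6	0.05	-0.22	3.42
TCG	39.3	-1.5	1.9	-0.28	0.09	3.37	36.1	0	5.4	0	0.41	3.39
TCT	39.3	-1.5	1.9	-0.28	0.09	3.37	31.5	-1.7	4.5	0.09	-0.25	3.34
TGA	37.3	0.5	4.7	0.09	0.53	3.33	39.3	-1.5	1.9	-0.28	0.09	3.37
TGC	37.3	0.5	4.7	0.09	0.53	3.33	38.3	0	0.3	0	-0.38	3.4
TGG	37.3	0.5	4.7	0.09	0.53	3.33	33.6	-0.1	3.6	0.05	-0.22	3.42
TGT	37.3	0.5	4.7	0.09	0.53	3.33	32.1	-0.1	0.7	0.13	-0.58	3.36
TTA	35.6	-1.4	0.7	-0.03	-0.08	3.27	37.8	0	3.3	0	0.05	3.42
TTC	35.6	-1.4	0.7	-0.03	-0.08	3.27	39.3	-1.5	1.9	-0.28	0.09	3.37
TTG	35.6	-1.4	0.7	-0.03	-0.08	3.27	37.3	0.5	4.7	0.09	0.53	3.33
TTT	35.6	-1.4	0.7	-0.03	-0.08	3.27	35.6	-1.4	0.7	-0.03	-0.08	3.27
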