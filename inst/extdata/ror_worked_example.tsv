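sample_id	platform	ror	ror_group	ror_ps	ror_ps_group
HCSC-0027	nanostring	51.10	med	43.42	med
HLPR-002	nanostring	43.57	med	23.44	med
HUGM-0022	nanostring	51.60	med	42.28	med
HUGM-0029	nanostring	73.51	high	68.98	high
HUGM-0047	nanostring	81.24	high	72.48	high
INEN-0017	nanostring	66.66	high	55.051	high
INEN-0021	nanostring	72.50	high	65.40	high
HCSC-0027	rnaseq	35.25	med	33.04	med
HLPR-002	rnaseq	16.87	low	10.68	low
HUGM-0022	rnaseq	40.68	med	32.44	med
HUGM-0029	rnaseq	75.02	high	69.59	high
HUGM-0047	rnaseq	73.73	high	69.58	high
INEN-0017	rnaseq	62.68	high	52.98	high
INEN-0021	rnaseq	66.98	high	64.52	high
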