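genotype	treatment	total_dry_weight	ground_biomass	k_content_pct
You06-71	lowK	1.92	1.62	1.40
You06-71	highK	2.85	2.29	2.71
ZhongDou33	lowK	1.59	1.31	1.44
ZhongDou33	highK	2.98	2.46	2.30
HengChun04-11	lowK	0.62	0.42	1.84
HengChun04-11	highK	2.46	1.98	2.42
ZhongHuang13	lowK	0.94	0.73	1.42
ZhongHuang13	highK	2.38	1.93	1.83
XuDou8	lowK	1.61	1.35	1.39
XuDou8	highK	3.18	2.57	2.28
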