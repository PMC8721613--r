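gene_id	A211	A211+ch	A283	A283+ch	ch
RPS4Y1	108.674500	67.975810	92.282690	43.432970	0.337399
DDX3Y	21.436540	11.931000	15.989530	8.763549	0.077968
PRKY	6.416036	3.243540	4.049743	2.343155	0.056736
USP9Y	3.647092	1.915803	1.484446	0.865820	0.023051
KDM5D	3.099356	2.289926	2.886254	1.857110	0.009570
ZFY	3.287543	1.731643	3.220577	1.739003	0.022190
EIF1AY	8.868548	4.705500	8.958360	5.544899	0.038423
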