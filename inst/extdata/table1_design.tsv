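sample_id	role	pair_id	sex	seeded_fraction
A211	msc_mono	A211	male	0.8
ch	ch_mono	A211	female	0.8
A211+ch	coculture	A211	mixed	0.8
A283	msc_mono	A283	male	0.8
ch	ch_mono	A283	female	0.8
A283+ch	coculture	A283	mixed	0.8
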