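category	unique_control	redundant_control	unique_drought	redundant_drought	unique_salt	redundant_salt
matched_est_gss	246723	2740263	279212	2714775	248892	2800217
matched_genome	1775856	8740467	2314399	9198501	1965288	8764559
matched_any	1847787	9229827	2398328	9719543	2040086	9281862
miRNA	29145	4265679	31229	3761665	31343	4114428
rRNA	87185	1230970	95647	1117486	80630	1038386
snRNA	1250	2041	1532	2619	1353	2338
snoRNA	486	749	611	1148	530	746
tRNA	8586	182011	10198	201042	7410	151590
unannotated	5598655	10427939	7511572	13725037	6256412	11631188
total	5725308	16109390	7650789	18808997	6377678	16938676
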