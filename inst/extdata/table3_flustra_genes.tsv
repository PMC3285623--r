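unit	A	G	C	T	at_percent	at_skew	gc_skew
atp6	0.213	0.225	0.123	0.439	65.2	-0.347	0.293
atp8	0.306	0.189	0.099	0.405	71.1	-0.139	0.313
cox1	0.227	0.219	0.135	0.419	64.6	-0.297	0.237
cox2	0.225	0.237	0.124	0.414	63.9	-0.296	0.313
cox3	0.196	0.266	0.11	0.426	62.2	-0.37	0.415
cob	0.225	0.214	0.13	0.43	65.5	-0.313	0.244
nad1	0.226	0.217	0.103	0.454	68	-0.335	0.356
nad2	0.246	0.217	0.104	0.434	68	-0.276	0.352
nad3	0.177	0.234	0.105	0.484	66.1	-0.464	0.381
nad4	0.214	0.219	0.106	0.462	67.6	-0.367	0.348
nad4L	0.212	0.242	0.072	0.474	68.6	-0.382	0.541
nad5	0.217	0.222	0.116	0.445	66.2	-0.344	0.314
nad6	0.187	0.224	0.085	0.503	69	-0.458	0.45
rrnS	0.336	0.215	0.142	0.306	64.2	0.047	0.204
rrnL	0.357	0.197	0.115	0.331	68.8	0.038	0.263
Entire genome	0.248	0.222	0.114	0.417	66.5	-0.254	0.321
Protein coding sequences	0.219	0.224	0.114	0.442	66.1	-0.337	0.325
1st codon position	0.27	0.257	0.117	0.358	62.8	-0.14	0.374
2nd codon position	0.169	0.183	0.186	0.462	63.1	-0.464	-0.008
3rd codon position	0.218	0.233	0.042	0.506	72.4	-0.398	0.695
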