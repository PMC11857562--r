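sample_id	Dpur	Ddis	TH11C	TH18CC	TH14B_Delta	TH8C	TH11CW	TH14B	Csub	Cpse	TH18B	TH19B	TH20A	Cbhu	Cpro	TH20C
Dpur	0	0.048	0.043	0.043	0.126	0.125	0.114	0.114	0.313	0.313	0.312	0.312	0.312	0.312	0.312	0.309
Ddis	0.048	0	0.035	0.035	0.119	0.12	0.123	0.123	0.318	0.316	0.313	0.313	0.313	0.313	0.313	0.313
TH11C	0.043	0.035	0	0	0.121	0.12	0.12	0.12	0.32	0.318	0.318	0.318	0.318	0.318	0.318	0.315
TH18CC	0.043	0.035	0	0	0.121	0.12	0.12	0.12	0.32	0.318	0.318	0.318	0.318	0.318	0.318	0.315
TH14B_Delta	0.126	0.119	0.121	0.121	0	0.005	0.039	0.039	0.325	0.328	0.326	0.326	0.326	0.326	0.326	0.325
TH8C	0.125	0.12	0.12	0.12	0.005	0	0.042	0.042	0.324	0.33	0.326	0.326	0.326	0.326	0.326	0.325
TH11CW	0.114	0.123	0.12	0.12	0.039	0.042	0	0	0.325	0.327	0.328	0.328	0.328	0.328	0.328	0.327
TH14B	0.114	0.123	0.12	0.12	0.039	0.042	0	0	0.325	0.327	0.328	0.328	0.328	0.328	0.328	0.327
Csub	0.313	0.318	0.32	0.32	0.325	0.324	0.325	0.325	0	0.009	0.006	0.006	0.006	0.006	0.006	0.007
Cpse	0.313	0.316	0.318	0.318	0.328	0.33	0.327	0.327	0.009	0	0.006	0.006	0.006	0.006	0.006	0.006
TH18B	0.312	0.313	0.318	0.318	0.326	0.326	0.328	0.328	0.006	0.006	0	0	0	0	0	0.002
TH19B	0.312	0.313	0.318	0.318	0.326	0.326	0.328	0.328	0.006	0.006	0	0	0	0	0	0.002
TH20A	0.312	0.313	0.318	0.318	0.326	0.326	0.328	0.328	0.006	0.006	0	0	0	0	0	0.002
Cbhu	0.312	0.313	0.318	0.318	0.326	0.326	0.328	0.328	0.006	0.006	0	0	0	0	0	0.002
Cpro	0.312	0.313	0.318	0.318	0.326	0.326	0.328	0.328	0.006	0.006	0	0	0	0	0	0.002
TH20C	0.309	0.313	0.315	0.315	0.325	0.325	0.327	0.327	0.007	0.006	0.002	0.002	0.002	0.002	0.002	0
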