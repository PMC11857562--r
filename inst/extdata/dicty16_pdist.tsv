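sample_id	Dpur	Ddis	TH11C	TH18CC	TH14B_Delta	TH8C	TH11CW	TH14B	Csub	Cpse	TH18B	TH19B	TH20A	Cbhu	Cpro	TH20C
Dpur	0	0.047	0.042	0.042	0.115	0.114	0.105	0.105	0.254	0.254	0.253	0.253	0.253	0.253	0.253	0.251
Ddis	0.047	0	0.034	0.034	0.11	0.111	0.113	0.113	0.257	0.255	0.254	0.254	0.254	0.254	0.254	0.254
TH11C	0.042	0.034	0	0	0.111	0.111	0.111	0.111	0.258	0.257	0.257	0.257	0.257	0.257	0.257	0.255
TH18CC	0.042	0.034	0	0	0.111	0.111	0.111	0.111	0.258	0.257	0.257	0.257	0.257	0.257	0.257	0.255
TH14B_Delta	0.115	0.11	0.111	0.111	0	0.005	0.038	0.038	0.262	0.264	0.263	0.263	0.263	0.263	0.263	0.262
TH8C	0.114	0.111	0.111	0.111	0.005	0	0.041	0.041	0.261	0.265	0.263	0.263	0.263	0.263	0.263	0.262
TH11CW	0.105	0.113	0.111	0.111	0.038	0.041	0	0	0.262	0.263	0.264	0.264	0.264	0.264	0.264	0.263
TH14B	0.105	0.113	0.111	0.111	0.038	0.041	0	0	0.262	0.263	0.264	0.264	0.264	0.264	0.264	0.263
Csub	0.254	0.257	0.258	0.258	0.262	0.261	0.262	0.262	0	0.009	0.006	0.006	0.006	0.006	0.006	0.007
Cpse	0.254	0.255	0.257	0.257	0.264	0.265	0.263	0.263	0.009	0	0.006	0.006	0.006	0.006	0.006	0.006
TH18B	0.253	0.254	0.257	0.257	0.263	0.263	0.264	0.264	0.006	0.006	0	0	0	0	0	0.002
TH19B	0.253	0.254	0.257	0.257	0.263	0.263	0.264	0.264	0.006	0.006	0	0	0	0	0	0.002
TH20A	0.253	0.254	0.257	0.257	0.263	0.263	0.264	0.264	0.006	0.006	0	0	0	0	0	0.002
Cbhu	0.253	0.254	0.257	0.257	0.263	0.263	0.264	0.264	0.006	0.006	0	0	0	0	0	0.002
Cpro	0.253	0.254	0.257	0.257	0.263	0.263	0.264	0.264	0.006	0.006	0	0	0	0	0	0.002
TH20C	0.251	0.254	0.255	0.255	0.262	0.262	0.263	0.263	0.007	0.006	0.002	0.002	0.002	0.002	0.002	0
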