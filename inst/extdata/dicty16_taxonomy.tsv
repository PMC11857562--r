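sample_id	species	genus	family	order
Dpur	Dictyostelium purpureum	Dictyostelium	Dictyosteliaceae	Dictyosteliales
Ddis	Dictyostelium discoideum	Dictyostelium	Dictyosteliaceae	Dictyosteliales
TH11C	Dictyostelium sp. TH11C	Dictyostelium	Dictyosteliaceae	Dictyosteliales
TH18CC	Dictyostelium sp. TH11C	Dictyostelium	Dictyosteliaceae	Dictyosteliales
TH14B_Delta	Raperostelium sp. TH14B (Delta)	Raperostelium	Raperosteliaceae	Dictyosteliales
TH8C	Raperostelium sp. TH8C	Raperostelium	Raperosteliaceae	Dictyosteliales
TH11CW	Raperostelium sp. TH14B	Raperostelium	Raperosteliaceae	Dictyosteliales
TH14B	Raperostelium sp. TH14B	Raperostelium	Raperosteliaceae	Dictyosteliales
Csub	Cavenderia subdiscoidea	Cavenderia	Cavenderiaceae	Acytosteliales
Cpse	Cavenderia pseudoaureostipes	Cavenderia	Cavenderiaceae	Acytosteliales
TH18B	Cavenderia ungulata	Cavenderia	Cavenderiaceae	Acytosteliales
TH19B	Cavenderia helicoidea	Cavenderia	Cavenderiaceae	Acytosteliales
TH20A	Cavenderia protumula	Cavenderia	Cavenderiaceae	Acytosteliales
Cbhu	Cavenderia bhumiboliana	Cavenderia	Cavenderiaceae	Acytosteliales
Cpro	Cavenderia protodigitata	Cavenderia	Cavenderiaceae	Acytosteliales
TH20C	Cavenderia parvibrachiata	Cavenderia	Cavenderiaceae	Acytosteliales
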