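species	genus	n_samples	asap_pattern	asap_groups	ml_topology	ml_support	bptp_pattern	bptp_groups
Dictyostelium ammophilum	Dictyostelium	2	MERGE	6	MONO	98	MERGE	7
Dictyostelium brefeldianum	Dictyostelium	2	MERGE	5	non-MONO	NA	MERGE	7
Dictyostelium chordatum	Dictyostelium	2	MONO	8	MONO	100	MERGE	7
Dictyostelium clavatum	Dictyostelium	2	MERGE	6	non-MONO	NA	MERGE	7
Dictyostelium dimigraformum	Dictyostelium	2	MONO	4	MONO	99	MERGE	7
Dictyostelium discoideum	Dictyostelium	17	SPLIT	1,2	non-MONO	NA	MERGE	7
Dictyostelium firmibasis	Dictyostelium	4	MONO	3	MONO	100	MERGE	7
Dictyostelium giganteum	Dictyostelium	4	MONO	9	MONO	92	MERGE	7
Dictyostelium leptosomopsis	Dictyostelium	3	MERGE	5	non-MONO	NA	MERGE	7
Dictyostelium longosporum	Dictyostelium	2	MERGE	6	non-MONO	NA	MERGE	7
Dictyostelium macrocephalum	Dictyostelium	2	multi-SPLIT	6,11	non-MONO	NA	MERGE	7
Dictyostelium mucoroides	Dictyostelium	8	multi-SPLIT	5,6,7	non-MONO	NA	MERGE	7
Dictyostelium multiforme	Dictyostelium	2	MERGE	6	non-MONO	NA	MERGE	7
Dictyostelium purpureum	Dictyostelium	23	SPLIT	12,13,14	MONO	81	MERGE	7
Dictyostelium septentrionalis	Dictyostelium	2	MONO	10	MONO	93	MERGE	7
Dictyostelium sphaerocephalum	Dictyostelium	6	multi-SPLIT	6,11	non-MONO	NA	MERGE	7
Polysphondylium patagonicum	Polysphondylium	2	MERGE	15	non-MONO	NA	MERGE	8
Polysphondylium violaceum	Polysphondylium	9	MERGE	15	non-MONO	NA	MERGE	8
Raperostelium minutum	Raperostelium	4	MONO	16	MONO	100	SPLIT	20,24,25
Raperostelium tenue	Raperostelium	3	SPLIT	17,18	non-MONO	NA	SPLIT	11,12
Coremiostelium polycephalum	Coremiostelium	5	SPLIT	19,20,21,22	MONO	87	SPLIT	13,21,22,23
Synstelium polycarpum	Synstelium	2	SPLIT	23,24	MONO	100	SPLIT	18,19
Rostrostelium ellipticum	Rostrostelium	2	MONO	34	MONO	100	MONO	4
Acytostelium amazonicum	Acytostelium	2	SPLIT	35,36	MONO	100	SPLIT	5,6
Acytostelium leptosomum	Acytostelium	2	SPLIT	37,38	MONO	99	SPLIT	2,3
Cavenderia aureostipes	Cavenderia	29	multi-SPLIT	39,40,41,42,44,45	non-MONO	NA	MERGE	1
Cavenderia bhumiboliana	Cavenderia	2	MERGE	45	non-MONO	NA	MERGE	1
Cavenderia cf. aureostipes	Cavenderia	19	multi-SPLIT	39,40,43,44,45,46,47,48	non-MONO	NA	MERGE	1
Cavenderia fasciculata	Cavenderia	8	multi-SPLIT	44,48	non-MONO	NA	MERGE	1
Cavenderia helicoidea	Cavenderia	2	MERGE	45	non-MONO	NA	MERGE	1
Cavenderia parvibrachiata	Cavenderia	3	MERGE	45	MONO	88	MERGE	1
Cavenderia protodigitata	Cavenderia	2	MERGE	45	non-MONO	NA	MERGE	1
Cavenderia protumula	Cavenderia	2	MERGE	45	non-MONO	NA	MERGE	1
Cavenderia pseudoaureostipes	Cavenderia	2	MERGE	45	MONO	100	MERGE	1
Cavenderia subdiscoidea	Cavenderia	2	MERGE	42	MONO	98	MERGE	1
Cavenderia ungulata	Cavenderia	2	MERGE	45	non-MONO	NA	MERGE	1
Heterostelium asymetricum	Heterostelium	2	MONO	29	MONO	100	MONO	17
Heterostelium boreale	Heterostelium	2	MONO	30	MONO	100	SPLIT	26,27
Heterostelium candidum	Heterostelium	3	multi-SPLIT	25,32	non-MONO	NA	multi-SPLIT	10,14
Heterostelium colligatum	Heterostelium	3	MERGE	33	non-MONO	NA	MERGE	15
Heterostelium oculare	Heterostelium	2	MONO	31	MONO	100	MONO	9
Heterostelium pallidum	Heterostelium	10	multi-SPLIT	25,26	non-MONO	NA	multi-SPLIT	10,16
Heterostelium tenuissimum	Heterostelium	3	multi-SPLIT	26,27,28	non-MONO	NA	MERGE	16
Heterostelium tikalense	Heterostelium	2	MERGE	33	non-MONO	NA	MERGE	15
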