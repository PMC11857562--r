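sample_id	group_id
Dictyostelium_ammophilum_01	6
Dictyostelium_ammophilum_02	6
Dictyostelium_brefeldianum_01	5
Dictyostelium_brefeldianum_02	5
Dictyostelium_chordatum_01	8
Dictyostelium_chordatum_02	8
Dictyostelium_clavatum_01	6
Dictyostelium_clavatum_02	6
Dictyostelium_dimigraformum_01	4
Dictyostelium_dimigraformum_02	4
Dictyostelium_discoideum_01	1
Dictyostelium_discoideum_02	2
Dictyostelium_discoideum_03	2
Dictyostelium_discoideum_04	2
Dictyostelium_discoideum_05	2
Dictyostelium_discoideum_06	2
Dictyostelium_discoideum_07	2
Dictyostelium_discoideum_08	2
Dictyostelium_discoideum_09	2
Dictyostelium_discoideum_10	2
Dictyostelium_discoideum_11	2
Dictyostelium_discoideum_12	2
Dictyostelium_discoideum_13	2
Dictyostelium_discoideum_14	2
Dictyostelium_discoideum_15	2
Dictyostelium_discoideum_16	2
Dictyostelium_discoideum_17	2
Dictyostelium_firmibasis_01	3
Dictyostelium_firmibasis_02	3
Dictyostelium_firmibasis_03	3
Dictyostelium_firmibasis_04	3
Dictyostelium_giganteum_01	9
Dictyostelium_giganteum_02	9
Dictyostelium_giganteum_03	9
Dictyostelium_giganteum_04	9
Dictyostelium_leptosomopsis_01	5
Dictyostelium_leptosomopsis_02	5
Dictyostelium_leptosomopsis_03	5
Dictyostelium_longosporum_01	6
Dictyostelium_longosporum_02	6
Dictyostelium_macrocephalum_01	6
Dictyostelium_macrocephalum_02	11
Dictyostelium_mucoroides_01	5
Dictyostelium_mucoroides_02	6
Dictyostelium_mucoroides_03	7
Dictyostelium_mucoroides_04	7
Dictyostelium_mucoroides_05	7
Dictyostelium_mucoroides_06	7
Dictyostelium_mucoroides_07	7
Dictyostelium_mucoroides_08	7
Dictyostelium_multiforme_01	6
Dictyostelium_multiforme_02	6
Dictyostelium_purpureum_01	12
Dictyostelium_purpureum_02	13
Dictyostelium_purpureum_03	14
Dictyostelium_purpureum_04	14
Dictyostelium_purpureum_05	14
Dictyostelium_purpureum_06	14
Dictyostelium_purpureum_07	14
Dictyostelium_purpureum_08	14
Dictyostelium_purpureum_09	14
Dictyostelium_purpureum_10	14
Dictyostelium_purpureum_11	14
Dictyostelium_purpureum_12	14
Dictyostelium_purpureum_13	14
Dictyostelium_purpureum_14	14
Dictyostelium_purpureum_15	14
Dictyostelium_purpureum_16	14
Dictyostelium_purpureum_17	14
Dictyostelium_purpureum_18	14
Dictyostelium_purpureum_19	14
Dictyostelium_purpureum_20	14
Dictyostelium_purpureum_21	14
Dictyostelium_purpureum_22	14
Dictyostelium_purpureum_23	14
Dictyostelium_septentrionalis_01	10
Dictyostelium_septentrionalis_02	10
Dictyostelium_sphaerocephalum_01	6
Dictyostelium_sphaerocephalum_02	11
Dictyostelium_sphaerocephalum_03	11
Dictyostelium_sphaerocephalum_04	11
Dictyostelium_sphaerocephalum_05	11
Dictyostelium_sphaerocephalum_06	11
Polysphondylium_patagonicum_01	15
Polysphondylium_patagonicum_02	15
Polysphondylium_violaceum_01	15
Polysphondylium_violaceum_02	15
Polysphondylium_violaceum_03	15
Polysphondylium_violaceum_04	15
Polysphondylium_violaceum_05	15
Polysphondylium_violaceum_06	15
Polysphondylium_violaceum_07	15
Polysphondylium_violaceum_08	15
Polysphondylium_violaceum_09	15
Raperostelium_minutum_01	16
Raperostelium_minutum_02	16
Raperostelium_minutum_03	16
Raperostelium_minutum_04	16
Raperostelium_tenue_01	17
Raperostelium_tenue_02	18
Raperostelium_tenue_03	18
Coremiostelium_polycephalum_01	19
Coremiostelium_polycephalum_02	20
Coremiostelium_polycephalum_03	21
Coremiostelium_polycephalum_04	22
Coremiostelium_polycephalum_05	22
Synstelium_polycarpum_01	23
Synstelium_polycarpum_02	24
Rostrostelium_ellipticum_01	34
Rostrostelium_ellipticum_02	34
Acytostelium_amazonicum_01	35
Acytostelium_amazonicum_02	36
Acytostelium_leptosomum_01	37
Acytostelium_leptosomum_02	38
Cavenderia_aureostipes_01	39
Cavenderia_aureostipes_02	40
Cavenderia_aureostipes_03	41
Cavenderia_aureostipes_04	42
Cavenderia_aureostipes_05	44
Cavenderia_aureostipes_06	45
Cavenderia_aureostipes_07	45
Cavenderia_aureostipes_08	45
Cavenderia_aureostipes_09	45
Cavenderia_aureostipes_10	45
Cavenderia_aureostipes_11	45
Cavenderia_aureostipes_12	45
Cavenderia_aureostipes_13	45
Cavenderia_aureostipes_14	45
Cavenderia_aureostipes_15	45
Cavenderia_aureostipes_16	45
Cavenderia_aureostipes_17	45
Cavenderia_aureostipes_18	45
Cavenderia_aureostipes_19	45
Cavenderia_aureostipes_20	45
Cavenderia_aureostipes_21	45
Cavenderia_aureostipes_22	45
Cavenderia_aureostipes_23	45
Cavenderia_aureostipes_24	45
Cavenderia_aureostipes_25	45
Cavenderia_aureostipes_26	45
Cavenderia_aureostipes_27	45
Cavenderia_aureostipes_28	45
Cavenderia_aureostipes_29	45
Cavenderia_bhumiboliana_01	45
Cavenderia_bhumiboliana_02	45
Cavenderia_cf_aureostipes_01	39
Cavenderia_cf_aureostipes_02	40
Cavenderia_cf_aureostipes_03	43
Cavenderia_cf_aureostipes_04	44
Cavenderia_cf_aureostipes_05	45
Cavenderia_cf_aureostipes_06	46
Cavenderia_cf_aureostipes_07	47
Cavenderia_cf_aureostipes_08	48
Cavenderia_cf_aureostipes_09	48
Cavenderia_cf_aureostipes_10	48
Cavenderia_cf_aureostipes_11	48
Cavenderia_cf_aureostipes_12	48
Cavenderia_cf_aureostipes_13	48
Cavenderia_cf_aureostipes_14	48
Cavenderia_cf_aureostipes_15	48
Cavenderia_cf_aureostipes_16	48
Cavenderia_cf_aureostipes_17	48
Cavenderia_cf_aureostipes_18	48
Cavenderia_cf_aureostipes_19	48
Cavenderia_fasciculata_01	44
Cavenderia_fasciculata_02	48
Cavenderia_fasciculata_03	48
Cavenderia_fasciculata_04	48
Cavenderia_fasciculata_05	48
Cavenderia_fasciculata_06	48
Cavenderia_fasciculata_07	48
Cavenderia_fasciculata_08	48
Cavenderia_helicoidea_01	45
Cavenderia_helicoidea_02	45
Cavenderia_parvibrachiata_01	45
Cavenderia_parvibrachiata_02	45
Cavenderia_parvibrachiata_03	45
Cavenderia_protodigitata_01	45
Cavenderia_protodigitata_02	45
Cavenderia_protumula_01	45
Cavenderia_protumula_02	45
Cavenderia_pseudoaureostipes_01	45
Cavenderia_pseudoaureostipes_02	45
Cavenderia_subdiscoidea_01	42
Cavenderia_subdiscoidea_02	42
Cavenderia_ungulata_01	45
Cavenderia_ungulata_02	45
Heterostelium_asymetricum_01	29
Heterostelium_asymetricum_02	29
Heterostelium_boreale_01	30
Heterostelium_boreale_02	30
Heterostelium_candidum_01	25
Heterostelium_candidum_02	32
Heterostelium_candidum_03	32
Heterostelium_colligatum_01	33
Heterostelium_colligatum_02	33
Heterostelium_colligatum_03	33
Heterostelium_oculare_01	31
Heterostelium_oculare_02	31
Heterostelium_pallidum_01	25
Heterostelium_pallidum_02	26
Heterostelium_pallidum_03	26
Heterostelium_pallidum_04	26
Heterostelium_pallidum_05	26
Heterostelium_pallidum_06	26
Heterostelium_pallidum_07	26
Heterostelium_pallidum_08	26
Heterostelium_pallidum_09	26
Heterostelium_pallidum_10	26
Heterostelium_tenuissimum_01	26
Heterostelium_tenuissimum_02	27
Heterostelium_tenuissimum_03	28
Heterostelium_tikalense_01	33
Heterostelium_tikalense_02	33
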