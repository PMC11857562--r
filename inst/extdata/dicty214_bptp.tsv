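sample_id	group_id
Dictyostelium_ammophilum_01	7
Dictyostelium_ammophilum_02	7
Dictyostelium_brefeldianum_01	7
Dictyostelium_brefeldianum_02	7
Dictyostelium_chordatum_01	7
Dictyostelium_chordatum_02	7
Dictyostelium_clavatum_01	7
Dictyostelium_clavatum_02	7
Dictyostelium_dimigraformum_01	7
Dictyostelium_dimigraformum_02	7
Dictyostelium_discoideum_01	7
Dictyostelium_discoideum_02	7
Dictyostelium_discoideum_03	7
Dictyostelium_discoideum_04	7
Dictyostelium_discoideum_05	7
Dictyostelium_discoideum_06	7
Dictyostelium_discoideum_07	7
Dictyostelium_discoideum_08	7
Dictyostelium_discoideum_09	7
Dictyostelium_discoideum_10	7
Dictyostelium_discoideum_11	7
Dictyostelium_discoideum_12	7
Dictyostelium_discoideum_13	7
Dictyostelium_discoideum_14	7
Dictyostelium_discoideum_15	7
Dictyostelium_discoideum_16	7
Dictyostelium_discoideum_17	7
Dictyostelium_firmibasis_01	7
Dictyostelium_firmibasis_02	7
Dictyostelium_firmibasis_03	7
Dictyostelium_firmibasis_04	7
Dictyostelium_giganteum_01	7
Dictyostelium_giganteum_02	7
Dictyostelium_giganteum_03	7
Dictyostelium_giganteum_04	7
Dictyostelium_leptosomopsis_01	7
Dictyostelium_leptosomopsis_02	7
Dictyostelium_leptosomopsis_03	7
Dictyostelium_longosporum_01	7
Dictyostelium_longosporum_02	7
Dictyostelium_macrocephalum_01	7
Dictyostelium_macrocephalum_02	7
Dictyostelium_mucoroides_01	7
Dictyostelium_mucoroides_02	7
Dictyostelium_mucoroides_03	7
Dictyostelium_mucoroides_04	7
Dictyostelium_mucoroides_05	7
Dictyostelium_mucoroides_06	7
Dictyostelium_mucoroides_07	7
Dictyostelium_mucoroides_08	7
Dictyostelium_multiforme_01	7
Dictyostelium_multiforme_02	7
Dictyostelium_purpureum_01	7
Dictyostelium_purpureum_02	7
Dictyostelium_purpureum_03	7
Dictyostelium_purpureum_04	7
Dictyostelium_purpureum_05	7
Dictyostelium_purpureum_06	7
Dictyostelium_purpureum_07	7
Dictyostelium_purpureum_08	7
Dictyostelium_purpureum_09	7
Dictyostelium_purpureum_10	7
Dictyostelium_purpureum_11	7
Dictyostelium_purpureum_12	7
Dictyostelium_purpureum_13	7
Dictyostelium_purpureum_14	7
Dictyostelium_purpureum_15	7
Dictyostelium_purpureum_16	7
Dictyostelium_purpureum_17	7
Dictyostelium_purpureum_18	7
Dictyostelium_purpureum_19	7
Dictyostelium_purpureum_20	7
Dictyostelium_purpureum_21	7
Dictyostelium_purpureum_22	7
Dictyostelium_purpureum_23	7
Dictyostelium_septentrionalis_01	7
Dictyostelium_septentrionalis_02	7
Dictyostelium_sphaerocephalum_01	7
Dictyostelium_sphaerocephalum_02	7
Dictyostelium_sphaerocephalum_03	7
Dictyostelium_sphaerocephalum_04	7
Dictyostelium_sphaerocephalum_05	7
Dictyostelium_sphaerocephalum_06	7
Polysphondylium_patagonicum_01	8
Polysphondylium_patagonicum_02	8
Polysphondylium_violaceum_01	8
Polysphondylium_violaceum_02	8
Polysphondylium_violaceum_03	8
Polysphondylium_violaceum_04	8
Polysphondylium_violaceum_05	8
Polysphondylium_violaceum_06	8
Polysphondylium_violaceum_07	8
Polysphondylium_violaceum_08	8
Polysphondylium_violaceum_09	8
Raperostelium_minutum_01	20
Raperostelium_minutum_02	24
Raperostelium_minutum_03	25
Raperostelium_minutum_04	25
Raperostelium_tenue_01	11
Raperostelium_tenue_02	12
Raperostelium_tenue_03	12
Coremiostelium_polycephalum_01	13
Coremiostelium_polycephalum_02	21
Coremiostelium_polycephalum_03	22
Coremiostelium_polycephalum_04	23
Coremiostelium_polycephalum_05	23
Synstelium_polycarpum_01	18
Synstelium_polycarpum_02	19
Rostrostelium_ellipticum_01	4
Rostrostelium_ellipticum_02	4
Acytostelium_amazonicum_01	5
Acytostelium_amazonicum_02	6
Acytostelium_leptosomum_01	2
Acytostelium_leptosomum_02	3
Cavenderia_aureostipes_01	1
Cavenderia_aureostipes_02	1
Cavenderia_aureostipes_03	1
Cavenderia_aureostipes_04	1
Cavenderia_aureostipes_05	1
Cavenderia_aureostipes_06	1
Cavenderia_aureostipes_07	1
Cavenderia_aureostipes_08	1
Cavenderia_aureostipes_09	1
Cavenderia_aureostipes_10	1
Cavenderia_aureostipes_11	1
Cavenderia_aureostipes_12	1
Cavenderia_aureostipes_13	1
Cavenderia_aureostipes_14	1
Cavenderia_aureostipes_15	1
Cavenderia_aureostipes_16	1
Cavenderia_aureostipes_17	1
Cavenderia_aureostipes_18	1
Cavenderia_aureostipes_19	1
Cavenderia_aureostipes_20	1
Cavenderia_aureostipes_21	1
Cavenderia_aureostipes_22	1
Cavenderia_aureostipes_23	1
Cavenderia_aureostipes_24	1
Cavenderia_aureostipes_25	1
Cavenderia_aureostipes_26	1
Cavenderia_aureostipes_27	1
Cavenderia_aureostipes_28	1
Cavenderia_aureostipes_29	1
Cavenderia_bhumiboliana_01	1
Cavenderia_bhumiboliana_02	1
Cavenderia_cf_aureostipes_01	1
Cavenderia_cf_aureostipes_02	1
Cavenderia_cf_aureostipes_03	1
Cavenderia_cf_aureostipes_04	1
Cavenderia_cf_aureostipes_05	1
Cavenderia_cf_aureostipes_06	1
Cavenderia_cf_aureostipes_07	1
Cavenderia_cf_aureostipes_08	1
Cavenderia_cf_aureostipes_09	1
Cavenderia_cf_aureostipes_10	1
Cavenderia_cf_aureostipes_11	1
Cavenderia_cf_aureostipes_12	1
Cavenderia_cf_aureostipes_13	1
Cavenderia_cf_aureostipes_14	1
Cavenderia_cf_aureostipes_15	1
Cavenderia_cf_aureostipes_16	1
Cavenderia_cf_aureostipes_17	1
Cavenderia_cf_aureostipes_18	1
Cavenderia_cf_aureostipes_19	1
Cavenderia_fasciculata_01	1
Cavenderia_fasciculata_02	1
Cavenderia_fasciculata_03	1
Cavenderia_fasciculata_04	1
Cavenderia_fasciculata_05	1
Cavenderia_fasciculata_06	1
Cavenderia_fasciculata_07	1
Cavenderia_fasciculata_08	1
Cavenderia_helicoidea_01	1
Cavenderia_helicoidea_02	1
Cavenderia_parvibrachiata_01	1
Cavenderia_parvibrachiata_02	1
Cavenderia_parvibrachiata_03	1
Cavenderia_protodigitata_01	1
Cavenderia_protodigitata_02	1
Cavenderia_protumula_01	1
Cavenderia_protumula_02	1
Cavenderia_pseudoaureostipes_01	1
Cavenderia_pseudoaureostipes_02	1
Cavenderia_subdiscoidea_01	1
Cavenderia_subdiscoidea_02	1
Cavenderia_ungulata_01	1
Cavenderia_ungulata_02	1
Heterostelium_asymetricum_01	17
Heterostelium_asymetricum_02	17
Heterostelium_boreale_01	26
Heterostelium_boreale_02	27
Heterostelium_candidum_01	10
Heterostelium_candidum_02	14
Heterostelium_candidum_03	14
Heterostelium_colligatum_01	15
Heterostelium_colligatum_02	15
Heterostelium_colligatum_03	15
Heterostelium_oculare_01	9
Heterostelium_oculare_02	9
Heterostelium_pallidum_01	10
Heterostelium_pallidum_02	16
Heterostelium_pallidum_03	16
Heterostelium_pallidum_04	16
Heterostelium_pallidum_05	16
Heterostelium_pallidum_06	16
Heterostelium_pallidum_07	16
Heterostelium_pallidum_08	16
Heterostelium_pallidum_09	16
Heterostelium_pallidum_10	16
Heterostelium_tenuissimum_01	16
Heterostelium_tenuissimum_02	16
Heterostelium_tenuissimum_03	16
Heterostelium_tikalense_01	15
Heterostelium_tikalense_02	15
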