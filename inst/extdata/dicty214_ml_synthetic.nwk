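(Acanthamoeba_castellanii,(((Dictyostelium_ammophilum_01,Dictyostelium_ammophilum_02),(Dictyostelium_chordatum_01,Dictyostelium_chordatum_02),(Dictyostelium_dimigraformum_01,Dictyostelium_dimigraformum_02),(Dictyostelium_firmibasis_01,Dictyostelium_firmibasis_02,Dictyostelium_firmibasis_03,Dictyostelium_firmibasis_04),(Dictyostelium_giganteum_01,Dictyostelium_giganteum_02,Dictyostelium_giganteum_03,Dictyostelium_giganteum_04),(Dictyostelium_purpureum_01,Dictyostelium_purpureum_02,Dictyostelium_purpureum_03,Dictyostelium_purpureum_04,Dictyostelium_purpureum_05,Dictyostelium_purpureum_06,Dictyostelium_purpureum_07,Dictyostelium_purpureum_08,Dictyostelium_purpureum_09,Dictyostelium_purpureum_10,Dictyostelium_purpureum_11,Dictyostelium_purpureum_12,Dictyostelium_purpureum_13,Dictyostelium_purpureum_14,Dictyostelium_purpureum_15,Dictyostelium_purpureum_16,Dictyostelium_purpureum_17,Dictyostelium_purpureum_18,Dictyostelium_purpureum_19,Dictyostelium_purpureum_20,Dictyostelium_purpureum_21,Dictyostelium_purpureum_22,Dictyostelium_purpureum_23),(Dictyostelium_septentrionalis_01,Dictyostelium_septentrionalis_02),(((((((((((((((((((((((((((((((((((((((((((Dictyostelium_brefeldianum_01,Dictyostelium_clavatum_01),Dictyostelium_discoideum_01),Dictyostelium_leptosomopsis_01),Dictyostelium_longosporum_01),Dictyostelium_macrocephalum_01),Dictyostelium_mucoroides_01),Dictyostelium_multiforme_01),Dictyostelium_sphaerocephalum_01),Dictyostelium_brefeldianum_02),Dictyostelium_clavatum_02),Dictyostelium_discoideum_02),Dictyostelium_leptosomopsis_02),Dictyostelium_longosporum_02),Dictyostelium_macrocephalum_02),Dictyostelium_mucoroides_02),Dictyostelium_multiforme_02),Dictyostelium_sphaerocephalum_02),Dictyostelium_discoideum_03),Dictyostelium_leptosomopsis_03),Dictyostelium_mucoroides_03),Dictyostelium_sphaerocephalum_03),Dictyostelium_discoideum_04),Dictyostelium_mucoroides_04),Dictyostelium_sphaerocephalum_04),Dictyostelium_discoideum_05),Dictyostelium_mucoroides_05),Dictyostelium_sphaerocephalum_05),Dictyostelium_discoideum_06),Dictyostelium_mucoroides_06),Dictyostelium_sphaerocephalum_06),Dictyostelium_discoideum_07),Dictyostelium_mucoroides_07),Dictyostelium_discoideum_08),Dictyostelium_mucoroides_08),Dictyostelium_discoideum_09),Dictyostelium_discoideum_10),Dictyostelium_discoideum_11),Dictyostelium_discoideum_12),Dictyostelium_discoideum_13),Dictyostelium_discoideum_14),Dictyostelium_discoideum_15),Dictyostelium_discoideum_16),Dictyostelium_discoideum_17)),((((((((((Polysphondylium_patagonicum_01,Polysphondylium_violaceum_01),Polysphondylium_patagonicum_02),Polysphondylium_violaceum_02),Polysphondylium_violaceum_03),Polysphondylium_violaceum_04),Polysphondylium_violaceum_05),Polysphondylium_violaceum_06),Polysphondylium_violaceum_07),Polysphondylium_violaceum_08),Polysphondylium_violaceum_09),(Raperostelium_tenue_01,((Raperostelium_minutum_01,Raperostelium_minutum_02,Raperostelium_minutum_03,Raperostelium_minutum_04),(Raperostelium_tenue_02,Raperostelium_tenue_03))),(Coremiostelium_polycephalum_01,Coremiostelium_polycephalum_02,Coremiostelium_polycephalum_03,Coremiostelium_polycephalum_04,Coremiostelium_polycephalum_05),(Synstelium_polycarpum_01,Synstelium_polycarpum_02),(Rostrostelium_ellipticum_01,Rostrostelium_ellipticum_02),((Acytostelium_amazonicum_01,Acytostelium_amazonicum_02),(Acytostelium_leptosomum_01,Acytostelium_leptosomum_02)),((Cavenderia_parvibrachiata_01,Cavenderia_parvibrachiata_02,Cavenderia_parvibrachiata_03),(Cavenderia_pseudoaureostipes_01,Cavenderia_pseudoaureostipes_02),(Cavenderia_subdiscoidea_01,Cavenderia_subdiscoidea_02),(((((((((((((((((((((((((((((((((((((((((((((((((((((((((((((((((Cavenderia_aureostipes_01,Cavenderia_bhumiboliana_01),Cavenderia_cf_aureostipes_01),Cavenderia_fasciculata_01),Cavenderia_helicoidea_01),Cavenderia_protodigitata_01),Cavenderia_protumula_01),Cavenderia_ungulata_01),Cavenderia_aureostipes_02),Cavenderia_bhumiboliana_02),Cavenderia_cf_aureostipes_02),Cavenderia_fasciculata_02),Cavenderia_helicoidea_02),Cavenderia_protodigitata_02),Cavenderia_protumula_02),Cavenderia_ungulata_02),Cavenderia_aureostipes_03),Cavenderia_cf_aureostipes_03),Cavenderia_fasciculata_03),Cavenderia_aureostipes_04),Cavenderia_cf_aureostipes_04),Cavenderia_fasciculata_04),Cavenderia_aureostipes_05),Cavenderia_cf_aureostipes_05),Cavenderia_fasciculata_05),Cavenderia_aureostipes_06),Cavenderia_cf_aureostipes_06),Cavenderia_fasciculata_06),Cavenderia_aureostipes_07),Cavenderia_cf_aureostipes_07),Cavenderia_fasciculata_07),Cavenderia_aureostipes_08),Cavenderia_cf_aureostipes_08),Cavenderia_fasciculata_08),Cavenderia_aureostipes_09),Cavenderia_cf_aureostipes_09),Cavenderia_aureostipes_10),Cavenderia_cf_aureostipes_10),Cavenderia_aureostipes_11),Cavenderia_cf_aureostipes_11),Cavenderia_aureostipes_12),Cavenderia_cf_aureostipes_12),Cavenderia_aureostipes_13),Cavenderia_cf_aureostipes_13),Cavenderia_aureostipes_14),Cavenderia_cf_aureostipes_14),Cavenderia_aureostipes_15),Cavenderia_cf_aureostipes_15),Cavenderia_aureostipes_16),Cavenderia_cf_aureostipes_16),Cavenderia_aureostipes_17),Cavenderia_cf_aureostipes_17),Cavenderia_aureostipes_18),Cavenderia_cf_aureostipes_18),Cavenderia_aureostipes_19),Cavenderia_cf_aureostipes_19),Cavenderia_aureostipes_20),Cavenderia_aureostipes_21),Cavenderia_aureostipes_22),Cavenderia_aureostipes_23),Cavenderia_aureostipes_24),Cavenderia_aureostipes_25),Cavenderia_aureostipes_26),Cavenderia_aureostipes_27),Cavenderia_aureostipes_28),Cavenderia_aureostipes_29)),((Heterostelium_asymetricum_01,Heterostelium_asymetricum_02),(Heterostelium_boreale_01,Heterostelium_boreale_02),(Heterostelium_oculare_01,Heterostelium_oculare_02),((((((((((((((((((((Heterostelium_candidum_01,Heterostelium_colligatum_01),Heterostelium_pallidum_01),Heterostelium_tenuissimum_01),Heterostelium_tikalense_01),Heterostelium_candidum_02),Heterostelium_colligatum_02),Heterostelium_pallidum_02),Heterostelium_tenuissimum_02),Heterostelium_tikalense_02),Heterostelium_candidum_03),Heterostelium_colligatum_03),Heterostelium_pallidum_03),Heterostelium_tenuissimum_03),Heterostelium_pallidum_04),Heterostelium_pallidum_05),Heterostelium_pallidum_06),Heterostelium_pallidum_07),Heterostelium_pallidum_08),Heterostelium_pallidum_09),Heterostelium_pallidum_10))));
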