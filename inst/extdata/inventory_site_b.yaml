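fields:
- cdw.drug_chemo_e01
- cdw.drug_chemo_e02
- cdw.drug_chemo_e03
- cdw.drug_chemo_e04
- cdw.drug_chemo_e05
- cdw.drug_chemo_e06
- cdw.drug_chemo_e07
- cdw.drug_chemo_e08
- cdw.drug_chemo_e09
- cdw.drug_chemo_e10
- cdw.drug_chemo_e11.a
- cdw.drug_chemo_e11.b
- cdw.drug_hsct_e01
- cdw.drug_hsct_e02
- cdw.drug_hsct_e03
- cdw.drug_hsct_e04
- cdw.drug_hsct_e05
- cdw.drug_hsct_e06
- cdw.drug_hsct_e07
- cdw.drug_other_e01
- cdw.drug_other_e02
- cdw.drug_other_e03
- cdw.drug_other_e04
- cdw.drug_other_e05
- cdw.drug_other_e06
- cdw.dx_all_e01
- cdw.dx_all_e02
- cdw.dx_all_e03
- cdw.dx_all_e04.a
- cdw.dx_all_e04.b
- cdw.dx_all_e05.a
- cdw.dx_all_e05.b
- cdw.dx_all_e06.a
- cdw.dx_all_e06.b
- cdw.dx_all_e07.report
- cdw.dx_other_e01
- cdw.dx_other_e02
- cdw.dx_other_e03
- cdw.dx_other_e04
- cdw.dx_other_e05.a
- cdw.dx_other_e05.b
- cdw.hsct_gvhd_e01
- cdw.hsct_gvhd_e02
- cdw.hsct_main_e01
- cdw.hsct_main_e02
- cdw.lab_bm_e01
- cdw.lab_bm_e02
- cdw.lab_bm_e03
- cdw.lab_bm_e04
- cdw.lab_bm_e05.a
- cdw.lab_bm_e05.b
- cdw.lab_bm_e06.a
- cdw.lab_bm_e06.b
- cdw.lab_bm_e07.a
- cdw.lab_bm_e07.b
- cdw.lab_bm_e08.a
- cdw.lab_bm_e08.b
- cdw.lab_bm_e09.report
- cdw.lab_chrom_e01
- cdw.lab_chrom_e02
- cdw.lab_chrom_e03
- cdw.lab_chrom_e04
- cdw.lab_chrom_e05
- cdw.lab_csf_e01
- cdw.lab_csf_e02
- cdw.lab_csf_e03
- cdw.lab_csf_e04
- cdw.lab_csf_e05
- cdw.lab_csf_e06
- cdw.lab_csf_e07.report
- cdw.lab_fish_e01
- cdw.lab_fish_e02
- cdw.lab_fish_e03
- cdw.lab_fish_e04
- cdw.lab_fish_e05
- cdw.lab_fish_e06
- cdw.lab_fish_e07
- cdw.lab_flow_e01
- cdw.lab_flow_e02
- cdw.lab_flow_e03
- cdw.lab_flow_e04
- cdw.lab_flow_e05
- cdw.lab_flow_e06
- cdw.lab_flow_e07
- cdw.lab_flow_e08
- cdw.lab_flow_e09
- cdw.lab_imaging_e01
- cdw.lab_imaging_e02
- cdw.lab_imaging_e03
- cdw.lab_imaging_e04
- cdw.lab_imaging_e05
- cdw.lab_imaging_e06
- cdw.lab_molgen_e01
- cdw.lab_molgen_e02
- cdw.lab_molgen_e03
- cdw.lab_molgen_e04
- cdw.lab_molgen_e05
- cdw.lab_molgen_e06
- cdw.lab_molgen_e07
- cdw.lab_molgen_e08
- cdw.lab_ngs_e01
- cdw.lab_ngs_e02
- cdw.lab_ngs_e03
- cdw.lab_ngs_e04
- cdw.lab_ngs_e05
- cdw.lab_ngs_e06
- cdw.lab_ngs_e07
- cdw.lab_ngs_e08
- cdw.lab_ngs_e09
- cdw.lab_pb_e01
- cdw.lab_pb_e02
- cdw.lab_pb_e03
- cdw.lab_pb_e04
- cdw.lab_pb_e05
- cdw.lab_pb_e06
- cdw.lab_pb_e07
- cdw.person_e01
- cdw.person_e02
- cdw.person_e03
- cdw.person_e04
- cdw.person_e05
- cdw.person_e06.a
- cdw.person_e06.b
- cdw.person_e07.a
- cdw.person_e07.b
- cdw.person_e08.a
- cdw.person_e08.b
- cdw.person_e09.a
- cdw.person_e09.b
- cdw.person_e10.a
- cdw.person_e10.b
- cdw.person_e11.a
- cdw.person_e11.b
- cdw.person_e12.a
- cdw.person_e12.b
- cdw.person_e13.a
- cdw.person_e13.b
- cdw.person_e14.a
- cdw.person_e14.b
- cdw.surg_all_e01
- cdw.surg_all_e02
- cdw.surg_all_e03
- cdw.surg_all_e04
- cdw.surg_all_e05
- cdw.surg_all_e06
- cdw.surg_other_e01
- cdw.surg_other_e02
- cdw.surg_other_e03
- cdw.surg_other_e04
- cdw.surg_other_e05
- cdw.surg_other_e06
- cdw.visit_e01
- cdw.visit_e02
- cdw.visit_e03
- cdw.visit_e04
- cdw.visit_e05
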