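key	value
patients_eligible	1368
patients_sequenced	1345
alterations_total	10805
alterations_oncogenic	7160
alterations_vus	3652
patients_on_label	169
patients_off_label	591
patients_resistance	80
patients_tmb_high	124
patients_msi_high	16
patients_combined_on_label	271
patients_brca12_lof	50
patients_hrr_lof	296
patients_high_risk_hrr	72
ovarian_n	70
ovarian_high_gloh	36
ovarian_parp_eligible	40
msi_comparator_positive	17
msi_comparator_negative	49
msi_detected_positive	17
msi_correct_negative	48
her2_fish_positive	12
her2_ngs_positive_of_fish_positive	10
her2_fish_negative	10
her2_ngs_negative_of_fish_negative	10
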